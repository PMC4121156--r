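# Synthetic scene generator: parametric walking humanoid under a pinhole
# camera, with ground-truth silhouette, cast shadow and projected extremes.
# The humanoid is a stack of axis-aligned primitives (head ellipse with a
# tapering neck, shouldered torso with a waist, two legs whose spread varies
# sinusoidally with the stride phase); the pipeline only ever consumes
# silhouettes, projections and widths, so no photorealism is attempted.

# Flat surface colours (8-bit RGB). The body is strongly chromatic against the
# achromatic floor so that true-body pixels carry a large chromaticity
# difference while cast shadows change brightness only.
.scene_colors <- list(
  background = c(120, 120, 120),
  head       = c(50, 35, 28),    # dark hair
  torso      = c(150, 25, 25),   # saturated red shirt
  legs       = c(25, 25, 160),   # saturated blue trousers
  backpack   = c(40, 120, 40)    # dark green pack
)

# Generative mass link constant (kg per cm^2): maps the height envelope
# 144-197 cm crossed with the default width envelope into 40-119 kg.
.mass_link_k <- 0.0165

#' Body shape and mass parameters of a synthetic subject
#'
#' Proportions default to a stylized adult: head 15\%, torso 35\%, legs 50\%
#' of stature. Widths are the maximal extents of each primitive in cm.
#'
#' @param subject_id identifier (coerced to character).
#' @param height_cm stature in cm; the generator emulates a 144-197 cm cohort.
#' @param mass_kg body mass in kg, or `NULL` if to be assigned later via
#'   [ground_truth_weight()].
#' @param head_frac,torso_frac,leg_frac unitless proportions of stature;
#'   must sum to 1.
#' @param head_width_cm,shoulder_width_cm,torso_width_cm,leg_width_cm maximal
#'   widths in cm of head, shoulders, waist and one leg. The waist must be
#'   narrower than the shoulders and than the two legs together so that the
#'   horizontal-projection minima mark the neck and waist.
#' @param stride_amplitude_cm peak foot separation during the stride, cm.
#' @param clothes_dilation_px horizontal silhouette dilation (loose clothes),
#'   integer pixels >= 0.
#' @param backpack logical; render an attached pack on the torso back.
#' @return An object of class `body_params`.
#' @export
body_params <- function(subject_id, height_cm, mass_kg = NULL,
                        head_frac = 0.15, torso_frac = 0.35, leg_frac = 0.50,
                        head_width_cm = 15, shoulder_width_cm = 44,
                        torso_width_cm = 28, leg_width_cm = 15,
                        stride_amplitude_cm = 45, clothes_dilation_px = 0L,
                        backpack = FALSE) {
  if (height_cm <= 0) stopf("height_cm must be positive")
  if (!is.null(mass_kg) && mass_kg <= 0) stopf("mass_kg must be positive")
  if (abs(head_frac + torso_frac + leg_frac - 1) > 1e-8) {
    stopf("head_frac + torso_frac + leg_frac must equal 1")
  }
  widths <- c(head_width_cm, shoulder_width_cm, torso_width_cm, leg_width_cm)
  if (any(widths <= 0)) stopf("all widths must be positive")
  if (clothes_dilation_px < 0) stopf("clothes_dilation_px must be >= 0")
  structure(list(
    subject_id = as.character(subject_id), height_cm = height_cm,
    mass_kg = mass_kg, head_frac = head_frac, torso_frac = torso_frac,
    leg_frac = leg_frac, head_width_cm = head_width_cm,
    shoulder_width_cm = shoulder_width_cm, torso_width_cm = torso_width_cm,
    leg_width_cm = leg_width_cm, stride_amplitude_cm = stride_amplitude_cm,
    clothes_dilation_px = as.integer(clothes_dilation_px),
    backpack = isTRUE(backpack)
  ), class = "body_params")
}

#' Pinhole camera geometry
#'
#' A level camera (zero pitch and roll), so the horizon coincides with the
#' principal row. Defaults reproduce the reference acquisition setup scaled
#' down by 4: camera 120 cm above the ground plane, subject 700 cm away,
#' 360 x 270 image with the horizon at the centre row.
#'
#' @param camera_height_cm reference camera height above the ground, cm.
#' @param subject_distance_cm subject plane distance from the camera, cm.
#' @param focal_px focal length in pixels.
#' @param image_width_px,image_height_px image dimensions.
#' @param horizon_row_px row of the horizontal vanishing line (symbol Y).
#' @return An object of class `camera_geometry`.
#' @export
camera_geometry <- function(camera_height_cm = 120, subject_distance_cm = 700,
                            focal_px = 600, image_width_px = 360,
                            image_height_px = 270, horizon_row_px = 135) {
  if (camera_height_cm <= 0) stopf("camera_height_cm must be positive")
  if (focal_px <= 0) stopf("focal_px must be positive")
  if (horizon_row_px < 0 || horizon_row_px >= image_height_px) {
    stopf("horizon_row_px must lie inside the image")
  }
  structure(list(
    camera_height_cm = camera_height_cm,
    subject_distance_cm = subject_distance_cm, focal_px = focal_px,
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    horizon_row_px = horizon_row_px
  ), class = "camera_geometry")
}

# Width profile of the humanoid (cm) at normalized body depth t in [0, 1]
# measured from the top of the head. Returns a list of horizontal intervals
# [left, right] in cm relative to the body axis.
body_intervals_cm <- function(body, t, stride_phase) {
  hf <- body$head_frac
  tf <- body$torso_frac
  if (t < hf) {                                   # head + neck
    u <- t / hf
    w_ell <- body$head_width_cm * sqrt(max(0, 1 - (2 * u - 1)^2))
    w_neck <- 0.4 * body$head_width_cm
    w <- w_ell
    if (u > 0.7) {
      # strictly decreasing taper to the neck: unique projection minimum
      w_lin <- 0.916 * body$head_width_cm +
        (w_neck - 0.916 * body$head_width_cm) * (u - 0.7) / 0.3
      w <- max(w_ell, w_lin)
    }
    w <- max(w, 2)                                # keep the crown rasterizable
    return(list(c(-w / 2, w / 2)))
  }
  if (t < hf + tf) {                              # shouldered torso with waist
    u <- (t - hf) / tf
    ws <- body$shoulder_width_cm
    ww <- body$torso_width_cm
    wm <- ww + 6
    w <- if (u <= 0.1) {
      ws
    } else if (u <= 0.8) {
      ws + (wm - ws) * (u - 0.1) / 0.7
    } else {
      wm + (ww - wm) * (u - 0.8) / 0.2            # steep taper into the waist
    }
    iv <- c(-w / 2, w / 2)
    if (body$backpack && u >= 0.15 && u <= 0.65) {
      depth <- 12 * sqrt(max(0, 1 - ((u - 0.4) / 0.25)^2))
      iv[1] <- iv[1] - depth
    }
    return(list(iv))
  }
  u <- (t - hf - tf) / body$leg_frac              # legs, spread grows downward
  sep <- body$stride_amplitude_cm * abs(sin(stride_phase)) * u
  lw <- body$leg_width_cm
  c1 <- -(lw / 2 + sep / 2)
  c2 <- +(lw / 2 + sep / 2)
  if (c2 - c1 <= lw) {                            # merged at the hip
    return(list(c(c1 - lw / 2, c2 + lw / 2)))
  }
  list(c(c1 - lw / 2, c1 + lw / 2), c(c2 - lw / 2, c2 + lw / 2))
}

# Rasterize one silhouette. Returns mask plus part labels (1 head, 2 torso,
# 3 legs, 4 backpack) and the exact projected extremes.
render_silhouette <- function(body, camera, stride_phase, lateral_cm = 0) {
  H <- camera$image_height_px
  W <- camera$image_width_px
  f <- camera$focal_px
  d <- camera$subject_distance_cm
  s <- f / d                                       # px per cm on subject plane
  top_f <- camera$horizon_row_px +
    f * (camera$camera_height_cm - body$height_cm) / d
  bot_f <- camera$horizon_row_px + f * camera$camera_height_cm / d
  # nearest-row rasterization keeps both extremes within half a pixel of the
  # exact projection, so the projected span is within 1 px of f*H/d
  r0 <- round(top_f)
  r1 <- round(bot_f)
  if (r0 < 1 || r1 > H) stopf("subject out of view (rows %d..%d)", r0, r1)
  center <- W / 2 + 0.5 + s * lateral_cm
  mask <- matrix(0L, H, W)
  part <- matrix(0L, H, W)
  hf <- body$head_frac
  tf <- body$torso_frac
  for (r in r0:r1) {
    t <- clamp((r - top_f) / (bot_f - top_f), 0, 1)
    ivs <- body_intervals_cm(body, t, stride_phase)
    pt <- if (t < hf) 1L else if (t < hf + tf) 2L else 3L
    for (iv in ivs) {
      c0 <- ceiling(center + iv[1] * s)
      c1c <- floor(center + iv[2] * s)
      if (c1c < c0) c0 <- c1c <- round(center + mean(iv) * s)
      if (c0 < 1 || c1c > W) stopf("subject out of view (cols %d..%d)", c0, c1c)
      mask[r, c0:c1c] <- 1L
      part[r, c0:c1c] <- pt
      if (pt == 2L && body$backpack) {
        # label the protruding pack region for colouring
        edge <- ceiling(center - body_torso_halfwidth(body, t) * s)
        if (c0 < edge) part[r, c0:(edge - 1)] <- 4L
      }
    }
  }
  if (body$clothes_dilation_px > 0) {
    k <- body$clothes_dilation_px
    below <- part != 1L & mask == 1L
    se <- matrix(1, 1, 2 * k + 1)
    dil <- as_mask(EBImage::dilate(below * 1, se))
    grown <- dil == 1L & mask == 0L
    mask[grown] <- 1L
    part[grown] <- 2L
    part[grown & row(mask) / H > 0.6] <- 3L       # crude relabel for trousers
  }
  # ground-truth extremes are the exact projections (fractional rows); the
  # rasterized mask rows are within half a pixel of them
  list(mask = mask, part = part, top_f = top_f, bot_f = bot_f,
       gt_top_row = top_f, gt_bottom_row = bot_f, center_col = center)
}

# Torso half-width (cm) before the backpack extension, used for labelling.
body_torso_halfwidth <- function(body, t) {
  u <- (t - body$head_frac) / body$torso_frac
  ws <- body$shoulder_width_cm
  ww <- body$torso_width_cm
  wm <- ww + 6
  w <- if (u <= 0.1) ws else if (u <= 0.8) {
    ws + (wm - ws) * (u - 0.1) / 0.7
  } else {
    wm + (ww - wm) * (u - 0.8) / 0.2
  }
  w / 2
}

shadow_ellipse <- function(seq_info, camera) {
  H <- camera$image_height_px
  W <- camera$image_width_px
  rc <- seq_info$bot_f
  cc <- seq_info$center_col + 30
  a <- 6                                           # row semi-axis
  b <- 32                                          # col semi-axis
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  ell <- ((rows - rc) / a)^2 + ((cols - cc) / b)^2 <= 1
  sh <- matrix(0L, H, W)
  sh[ell] <- 1L
  sh[seq_info$mask == 1L] <- 0L
  sh
}

#' Render a ground-truthed synthetic walking sequence
#'
#' Frames are the ones a 1 fps decimation of high-frame-rate footage would
#' retain: between consecutive rendered frames the stride phase advances by a
#' large, incommensurate step, emulating the large stride fluctuation of
#' low-frame-rate video, and the subject translates laterally across the view.
#'
#' @param body a [body_params()] object.
#' @param camera a [camera_geometry()] object.
#' @param n_frames number of retained frames (>= 1).
#' @param fps_decimation source-frames-per-retained-frame factor; 50 models
#'   1 fps selection from 50 fps footage.
#' @param seed integer seed; the sequence is bit-identical for a fixed seed.
#' @param rgb render RGB background/frame images (set `FALSE` for mask-only
#'   sequences, which is much lighter).
#' @param shadow render a cast shadow region at the feet.
#' @param shadow_attenuation per-channel brightness factor in (0,1) applied
#'   under the shadow; chromaticity is preserved.
#' @param pixel_noise_sd sensor noise standard deviation, 8-bit levels.
#' @param lateral_range_cm start and end lateral offsets of the walk (cm
#'   relative to the optical axis); `c(0, 0)` renders a stationary pose.
#' @return An object of class `scene_sequence`: a list with `frames` (list of
#'   `scene_frame` objects with fields `background`, `frame`, `gt_mask`,
#'   `gt_shadow`, `gt_top_row`, `gt_bottom_row`, `stride_phase`), `body`,
#'   `camera`. The ground-truth extreme rows are the exact (fractional)
#'   pinhole projections, so the metrology cross-ratio inverts them exactly;
#'   the rasterized mask extremes lie within half a pixel of them.
#' @export
render_sequence <- function(body, camera, n_frames, fps_decimation = 50,
                            seed = 1, rgb = TRUE, shadow = TRUE,
                            shadow_attenuation = 0.6, pixel_noise_sd = 2,
                            lateral_range_cm = c(-60, 60)) {
  if (n_frames < 1) stopf("n_frames must be >= 1")
  if (shadow && (shadow_attenuation <= 0 || shadow_attenuation >= 1)) {
    stopf("shadow_attenuation must lie in (0, 1)")
  }
  H <- camera$image_height_px
  W <- camera$image_width_px
  with_seed(seed, {
    phi0 <- runif(1, 0, 2 * pi)
    # stride cycle ~1.2 s at 50 source fps -> phase step per source frame
    dphi <- 2 * pi / 60 * fps_decimation
    background <- NULL
    if (rgb) {
      background <- array(0, c(H, W, 3))
      tex <- matrix(rnorm(H * W, 0, 3), H, W)
      for (ch in 1:3) {
        background[, , ch] <- clamp(.scene_colors$background[ch] + tex, 0, 255)
      }
    }
    lat <- if (n_frames == 1) {
      mean(lateral_range_cm)
    } else {
      seq(lateral_range_cm[1], lateral_range_cm[2], length.out = n_frames)
    }
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      phase <- phi0 + (i - 1) * dphi
      sil <- render_silhouette(body, camera, phase, lat[i])
      gt_shadow <- if (shadow) shadow_ellipse(sil, camera) else matrix(0L, H, W)
      fr <- NULL
      if (rgb) {
        fr <- background
        for (p in 1:4) {
          sel <- sil$part == p
          if (!any(sel)) next
          col <- .scene_colors[[c("head", "torso", "legs", "backpack")[p]]]
          for (ch in 1:3) {
            pl <- fr[, , ch]
            pl[sel] <- col[ch]
            fr[, , ch] <- pl
          }
        }
        if (pixel_noise_sd > 0) {
          fr <- clamp(fr + array(rnorm(H * W * 3, 0, pixel_noise_sd),
                                 c(H, W, 3)), 0, 255)
        }
      }
      sf <- structure(list(
        background = background, frame = fr, gt_mask = sil$mask,
        gt_shadow = gt_shadow, gt_top_row = sil$gt_top_row,
        gt_bottom_row = sil$gt_bottom_row, stride_phase = phase,
        subject_id = body$subject_id, frame_index = i
      ), class = "scene_frame")
      if (rgb && shadow) sf <- make_shadowed_frame(sf, shadow_attenuation)
      frames[[i]] <- sf
    }
    structure(list(frames = frames, body = body, camera = camera),
              class = "scene_sequence")
  })
}

#' Apply a brightness-only cast shadow to a scene frame
#'
#' Pixels under the frame's ground-truth shadow region have all three channels
#' multiplied by `shadow_attenuation`; chromaticity is preserved exactly.
#'
#' @param frame a `scene_frame`.
#' @param shadow_attenuation factor in (0, 1).
#' @return The frame with the shadow stamped into its `frame` image.
#' @export
make_shadowed_frame <- function(frame, shadow_attenuation) {
  if (shadow_attenuation <= 0 || shadow_attenuation >= 1) {
    stopf("shadow_attenuation must lie in (0, 1)")
  }
  if (is.null(frame$frame) || !any(frame$gt_shadow == 1L)) return(frame)
  sel <- frame$gt_shadow == 1L
  for (ch in 1:3) {
    pl <- frame$frame[, , ch]
    pl[sel] <- pl[sel] * shadow_attenuation
    frame$frame[, , ch] <- pl
  }
  frame
}

#' Ground-truth mass from the generative silhouette-mass link
#'
#' Mass is `k * height_cm * mean(width_cm) + noise` with
#' `k = 0.0165` kg/cm^2, fixed so the 144-197 cm stature envelope crossed
#' with the default width envelope maps into 40-119 kg. This link is an
#' artifact convention making the silhouette features informative about mass;
#' it is not a physiological model.
#'
#' @param body a [body_params()] object.
#' @param noise_sd_kg standard deviation of additive Gaussian noise, kg.
#' @param seed seed for the noise draw (ignored when `noise_sd_kg = 0`).
#' @return mass in kg.
#' @export
ground_truth_weight <- function(body, noise_sd_kg = 0, seed = NULL) {
  if (noise_sd_kg < 0) stopf("noise_sd_kg must be >= 0")
  mw <- mean(c(body$head_width_cm, body$shoulder_width_cm,
               body$torso_width_cm, body$leg_width_cm))
  base <- .mass_link_k * body$height_cm * mw
  if (noise_sd_kg == 0) return(base)
  with_seed(seed, base + rnorm(1, 0, noise_sd_kg))
}

#' Sample a cohort of synthetic subjects
#'
#' Statures are uniform on the 144-197 cm envelope; widths are uniform on
#' ranges chosen so the mass link stays inside 40-119 kg, with the waist
#' clamped below the two-leg width so the horizontal-projection waist minimum
#' is well defined. Masses are assigned by [ground_truth_weight()].
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param noise_sd_kg mass noise passed to [ground_truth_weight()].
#' @param height_range stature envelope in cm.
#' @return list of `body_params`, each with `mass_kg` set.
#' @export
sample_cohort <- function(n, seed = 1, noise_sd_kg = 2,
                          height_range = c(144, 197)) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      h <- runif(1, height_range[1], height_range[2])
      hw <- runif(1, 14, 18)
      sw <- runif(1, 36, 50)
      lw <- runif(1, 12, 18)
      tw <- min(runif(1, 24, 34), 2 * lw - 2)
      b <- body_params(
        subject_id = sprintf("S%03d", i), height_cm = h,
        head_width_cm = hw, shoulder_width_cm = sw, torso_width_cm = tw,
        leg_width_cm = lw,
        stride_amplitude_cm = runif(1, 30, 55)
      )
      b$mass_kg <- ground_truth_weight(b, noise_sd_kg,
                                       seed = sample.int(2^31 - 1, 1))
      b
    })
  })
}
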