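# Silhouette extraction: squared RGB differencing, suppressed Otsu
# thresholding, brightness/chromaticity shadow removal, morphological cleanup.

#' Parameters of the foreground / shadow model
#'
#' @param suppression_c threshold suppression factor c > 1: the Otsu threshold
#'   is divided by `c` to loosen the segmentation and recover dim foreground
#'   (typically the leg region).
#' @param brightness_threshold lighting-change threshold T on the combined
#'   brightness/chromaticity difference B_D: masked pixels with B_D < T are
#'   treated as lighting changes (shadows) and removed. A cast shadow with
#'   per-channel attenuation a has B_D about `-log(a)`, so T must exceed
#'   `-log(a)` of the deepest shadow to be removed while staying below the
#'   B_D of true-body pixels. The default 0.6 removes shadows attenuated to
#'   60\% and above.
#' @param min_component_area_px connected components smaller than this are
#'   dropped during cleanup; `NULL` means 0.01\% of the image pixels.
#' @param morphology_radius_px radius of the opening brush.
#' @return An object of class `shadow_model_params`.
#' @export
shadow_model_params <- function(suppression_c = 2, brightness_threshold = 0.6,
                                min_component_area_px = NULL,
                                morphology_radius_px = 1) {
  if (suppression_c <= 1) stopf("suppression_c must be greater than 1")
  if (brightness_threshold <= 0) stopf("brightness_threshold must be > 0")
  structure(list(
    suppression_c = suppression_c,
    brightness_threshold = brightness_threshold,
    min_component_area_px = min_component_area_px,
    morphology_radius_px = as.integer(morphology_radius_px)
  ), class = "shadow_model_params")
}

#' Squared RGB difference image
#'
#' `D(x, y) = sum over R,G,B of (bg - frame)^2`, the per-pixel sum of squared
#' band differences. Nonnegative and symmetric in its arguments.
#'
#' @param background,frame RGB arrays (rows x cols x 3, intensities 0-255).
#' @return numeric matrix D.
#' @export
rgb_difference <- function(background, frame) {
  if (!identical(dim(background), dim(frame)) || length(dim(frame)) != 3 ||
      dim(frame)[3] != 3) {
    stopf("background and frame must be RGB arrays of identical dimensions")
  }
  D <- (background[, , 1] - frame[, , 1])^2 +
    (background[, , 2] - frame[, , 2])^2 +
    (background[, , 3] - frame[, , 3])^2
  dim(D) <- dim(frame)[1:2]
  D
}

#' Otsu threshold of a 256-level image
#'
#' Returns the level `k` in 0..255 maximizing the between-class variance of
#' the split into classes `<= k` and `> k`. Ties are broken by the smallest
#' level so the result is deterministic.
#'
#' @param image numeric matrix of values in [0, 255] (binned to integers).
#' @return integer threshold level.
#' @export
otsu_threshold <- function(image) {
  lv <- clamp(floor(image), 0, 255)
  if (length(unique(as.vector(lv))) < 2) {
    stopf("degenerate histogram: image has a single grey level")
  }
  h <- tabulate(as.vector(lv) + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w1 <- 1 - w0
  # between-class variance sigma_b^2(k) = (mu_t*w0 - mu)^2 / (w0*w1)
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  sigma <- ifelse(den > 0, num / den, -Inf)
  as.integer(levels[which.max(sigma)])   # which.max -> smallest maximizer
}

# Linear rescale of an unbounded nonnegative difference image onto [0, 255],
# anchored at zero so D > 0 maps to q > 0.
rescale_256 <- function(D) {
  m <- max(D)
  if (m <= 0) return(D)
  D * (255 / m)
}

#' Raw foreground mask by suppressed Otsu thresholding
#'
#' The difference image is linearly rescaled to [0, 255]; Otsu defines
#' T_thres on this scale, and the mask is `q > T_thres / c` with the
#' suppression parameter c > 1 loosening the cut.
#'
#' @param D difference image from [rgb_difference()].
#' @param params [shadow_model_params()].
#' @return 0/1 integer mask with attribute `stage = "raw"` and the Otsu
#'   threshold in attribute `t_thres`.
#' @export
foreground_mask <- function(D, params = shadow_model_params()) {
  q <- rescale_256(D)
  t_thres <- otsu_threshold(q)
  mask <- as_mask((q > t_thres / params$suppression_c) * 1L)
  attr(mask, "stage") <- "raw"
  attr(mask, "t_thres") <- t_thres
  mask
}

# Brightness (mean of R,G,B) and normalized-GB chromaticity with an additive
# epsilon of one intensity level, so black pixels never produce infinities.
brightness_chroma <- function(img) {
  eps <- 1
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  s <- r + g + b + eps
  list(I = (r + g + b) / 3 + eps, cg = g / s, cb = b / s)
}

#' Remove shadow pixels from a raw foreground mask
#'
#' Computes the combined brightness and chromaticity difference
#' `B_D = |log(I_b / I_f)| + D_FB` where I_b, I_f are the background and
#' frame brightness (mean of R,G,B) and D_FB is the Euclidean distance
#' between the normalized-GB chromaticity coordinates of the two images.
#' Masked pixels with `B_D < T` are lighting changes (the shadow map is
#' `Shadow = F_M AND (B_D < T)`), and the output is
#' `F_M AND (1 - Shadow)` -- purely subtractive, so the result is always a
#' subset of the input mask.
#'
#' @param raw raw 0/1 mask from [foreground_mask()].
#' @param background,frame the RGB images the mask was derived from.
#' @param params [shadow_model_params()]; `brightness_threshold` is T.
#' @return 0/1 mask with attribute `stage = "deshadowed"` and the removed
#'   shadow map in attribute `shadow`.
#' @export
remove_shadows <- function(raw, background, frame,
                           params = shadow_model_params()) {
  if (!identical(dim(raw), dim(background)[1:2])) {
    stopf("mask and images must share dimensions")
  }
  bg <- brightness_chroma(background)
  fg <- brightness_chroma(frame)
  d_fb <- sqrt((fg$cg - bg$cg)^2 + (fg$cb - bg$cb)^2)
  b_d <- abs(log(bg$I / fg$I)) + d_fb
  shadow <- as_mask((raw == 1L & b_d < params$brightness_threshold) * 1L)
  out <- as_mask((raw == 1L & shadow == 0L) * 1L)
  attr(out, "stage") <- "deshadowed"
  attr(out, "shadow") <- shadow
  out
}

#' Morphological cleanup of a foreground mask
#'
#' Opening with a disc of the configured radius followed by removal of
#' connected components below the minimum area. Both steps only ever remove
#' pixels, so the cleaned mask is a subset of its input.
#'
#' @param mask 0/1 mask.
#' @param params [shadow_model_params()].
#' @return 0/1 mask with attribute `stage = "cleaned"` (possibly empty).
#' @export
clean_foreground <- function(mask, params = shadow_model_params()) {
  m <- as_mask((mask == 1L) * 1L)
  r <- params$morphology_radius_px
  if (r > 0 && any(m == 1L)) {
    brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
    m <- as_mask(EBImage::opening(m, brush))
  }
  min_area <- params$min_component_area_px
  if (is.null(min_area)) min_area <- ceiling(1e-4 * length(m))
  if (min_area > 0 && any(m == 1L)) {
    lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_area)
    m2 <- matrix(0L, nrow(m), ncol(m))
    m2[lab %in% keep] <- 1L
    m <- m2
  }
  out <- as_mask(m)
  attr(out, "stage") <- "cleaned"
  out
}

#' Bounding rows of the largest connected component
#'
#' @param mask nonempty 0/1 mask.
#' @return An object of class `roi_bounds`: list with `top_row` (X_T) and
#'   `bottom_row` (X_B) of the largest component's bounding box.
#' @export
extract_roi <- function(mask) {
  if (!any(mask == 1L)) stopf("empty mask: no subject found")
  lab <- EBImage::bwlabel(as_mask((mask == 1L) * 1L))
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  rows <- which(apply(lab == big, 1, any))
  structure(list(top_row = min(rows), bottom_row = max(rows)),
            class = "roi_bounds")
}

#' Full silhouette extraction for one frame
#'
#' Convenience chain: [rgb_difference()], [foreground_mask()],
#' [remove_shadows()], [clean_foreground()].
#'
#' @inheritParams remove_shadows
#' @return cleaned 0/1 mask.
#' @export
extract_silhouette <- function(background, frame,
                               params = shadow_model_params()) {
  D <- rgb_difference(background, frame)
  raw <- foreground_mask(D, params)
  desh <- remove_shadows(raw, background, frame, params)
  clean_foreground(desh, params)
}
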