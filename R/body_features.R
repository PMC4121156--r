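# 13-feature body-measurement vector: head/torso/leg segmentation from
# horizontal-projection minima, pixel densities, silhouette size, weighted
# ratios, metric region lengths, head and shoulder widths, and min-max
# normalization for the weight regressor.

#' Horizontal projection profile of a silhouette
#'
#' `P_H(j)` is the per-row count of foreground pixels, taken over the ROI
#' rows (the silhouette's bounding rows by default). Its minima mark the neck
#' and the waist.
#'
#' @param mask 0/1 silhouette mask.
#' @param roi optional `roi_bounds`; defaults to [extract_roi()] of the mask.
#' @return integer vector of length `I` (ROI pixel height), with attribute
#'   `top_row` giving the absolute row of the first element.
#' @export
horizontal_projection <- function(mask, roi = NULL) {
  if (is.null(roi)) roi <- extract_roi(mask)
  rows <- roi$top_row:roi$bottom_row
  p <- as.integer(rowSums(mask[rows, , drop = FALSE] == 1L))
  attr(p, "top_row") <- roi$top_row
  p
}

#' Locate head and torso boundaries from projection minima
#'
#' The head boundary (neck) is the row of minimum `P_H` within 10-30\% of
#' the ROI rows; the torso boundary (waist) the minimum within 35-70\%.
#' Percentages are over ROI rows with the top at 0\%; ties take the smallest
#' row. Region pixel lengths `L_HP + L_TP + L_LP` always sum to the ROI
#' pixel height.
#'
#' @param p_h projection profile from [horizontal_projection()].
#' @param roi the `roi_bounds` the profile was computed over (optional if
#'   `p_h` carries its `top_row` attribute).
#' @return An object of class `region_segmentation`: list with
#'   `head_boundary_row`, `torso_boundary_row` (absolute rows), `l_hp`,
#'   `l_tp`, `l_lp`.
#' @export
locate_regions <- function(p_h, roi = NULL) {
  I <- length(p_h)
  if (I < 10) stopf("projection profile must span at least 10 rows")
  top <- if (!is.null(roi)) roi$top_row else attr(p_h, "top_row")
  if (is.null(top)) top <- 1L
  band <- function(lo, hi) {
    idx <- max(1L, round(lo * I)):min(I, round(hi * I))
    idx[which.min(p_h[idx])]          # which.min -> earliest row on ties
  }
  hb <- band(0.10, 0.30)
  tb <- band(0.35, 0.70)
  bottom <- top + I - 1L
  head_row <- top + hb - 1L
  torso_row <- top + tb - 1L
  structure(list(
    head_boundary_row = head_row, torso_boundary_row = torso_row,
    l_hp = hb,                        # rows top..head boundary inclusive
    l_tp = tb - hb,
    l_lp = I - tb
  ), class = "region_segmentation")
}

# Absolute row ranges of the three regions.
region_rows <- function(seg, roi) {
  list(
    head = roi$top_row:seg$head_boundary_row,
    torso = (seg$head_boundary_row + 1L):seg$torso_boundary_row,
    legs = (seg$torso_boundary_row + 1L):roi$bottom_row
  )
}

#' Pixel densities of the head, torso and leg regions
#'
#' Each density is the region's foreground pixel count divided by its pixel
#' length (rows), i.e. the region's mean width in pixels.
#'
#' @param mask 0/1 silhouette mask.
#' @param seg a `region_segmentation`.
#' @param roi the `roi_bounds`.
#' @return named numeric vector `c(h_feat, t_feat, l_feat)`.
#' @export
pixel_densities <- function(mask, seg, roi) {
  if (seg$l_hp <= 0 || seg$l_tp <= 0 || seg$l_lp <= 0) {
    stopf("zero-length region in segmentation")
  }
  rr <- region_rows(seg, roi)
  cnt <- function(rows) sum(mask[rows, , drop = FALSE] == 1L)
  c(h_feat = cnt(rr$head) / seg$l_hp,
    t_feat = cnt(rr$torso) / seg$l_tp,
    l_feat = cnt(rr$legs) / seg$l_lp)
}

#' Silhouette size feature
#'
#' Total foreground area divided by the ROI pixel height |X_T - X_B|: the
#' silhouette's mean width.
#'
#' @inheritParams pixel_densities
#' @return `w_feat` (pixels).
#' @export
silhouette_size <- function(mask, roi) {
  h <- abs(roi$top_row - roi$bottom_row)
  if (h == 0) stopf("zero ROI height")
  sum(mask == 1L) / h
}

#' Weighted region ratios
#'
#' `R_H = H^2/(T+L)`, `R_T = T^2/(H+L)`, `R_L = L^2/(H+T)` -- each region's
#' density squared over the sum of the other two, giving more significance
#' to the numerator. Homogeneous of degree 1 in a common density scale.
#'
#' @param h_feat,t_feat,l_feat region pixel densities.
#' @return named numeric vector `c(r_h, r_t, r_l)`.
#' @export
weighted_ratios <- function(h_feat, t_feat, l_feat) {
  dens <- c(h_feat, t_feat, l_feat)
  if (all(dens == 0)) stopf("degenerate silhouette: all densities zero")
  den <- c(t_feat + l_feat, h_feat + l_feat, h_feat + t_feat)
  if (any(den == 0)) stopf("degenerate silhouette: zero ratio denominator")
  c(r_h = h_feat^2 / den[1], r_t = t_feat^2 / den[2], r_l = l_feat^2 / den[3])
}

#' Metric lengths of the body regions
#'
#' Converts region pixel lengths to cm with the metrology scale `H_c / V`:
#' `L_L = (H_c/V) L_LP`, `L_T = (H_c/V)(L_TP + L_LP)`,
#' `L_H = (H_c/V)(|X_T - X_B| - (L_TP + L_LP))`. Note that `L_T` as defined
#' is cumulative (torso plus legs), so `L_H + L_T` equals the metric height
#' `O_H` exactly; this follows the printed definition and is kept verbatim.
#'
#' @param seg a `region_segmentation`.
#' @param roi the `roi_bounds`.
#' @param camera a [camera_geometry()].
#' @return named numeric vector `c(l_h_cm, l_t_cm, l_l_cm)`.
#' @export
region_lengths_cm <- function(seg, roi, camera) {
  v <- roi$bottom_row - camera$horizon_row_px
  if (v <= 0) stopf("V = X_B - Y must be positive")
  sc <- camera$camera_height_cm / v
  roi_h <- abs(roi$top_row - roi$bottom_row)
  tl <- seg$l_tp + seg$l_lp
  c(l_h_cm = sc * (roi_h - tl), l_t_cm = sc * tl, l_l_cm = sc * seg$l_lp)
}

# Maximum per-row foreground count of the largest connected component within
# a band of rows of the mask.
band_max_width <- function(mask, rows) {
  sub <- mask[rows, , drop = FALSE]
  if (!any(sub == 1L)) stopf("empty search band")
  lab <- matrix(as.integer(EBImage::bwlabel(as_mask(sub))), nrow(sub))
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  max(rowSums(lab == big))
}

#' Head and shoulder widths from connected components
#'
#' The head width `W_H` is the maximum per-row pixel count of the largest
#' connected component within the middle third of the head region's rows;
#' the shoulder width `W_S` is the same statistic within the first 10\% of
#' the torso rows.
#'
#' @inheritParams pixel_densities
#' @return named numeric vector `c(w_h_px, w_s_px)`.
#' @export
head_shoulder_widths <- function(mask, seg, roi) {
  rr <- region_rows(seg, roi)
  n_head <- length(rr$head)
  mid <- rr$head[max(1L, floor(n_head / 3)):min(n_head, ceiling(2 * n_head / 3))]
  n_torso <- length(rr$torso)
  shoulder <- rr$torso[1:max(1L, round(0.1 * n_torso))]
  c(w_h_px = band_max_width(mask, mid), w_s_px = band_max_width(mask, shoulder))
}

# Canonical feature order of the 13-vector.
feature_names <- c("o_h_cm", "h_feat", "t_feat", "l_feat", "w_feat",
                   "r_h", "r_t", "r_l", "l_h_cm", "l_t_cm", "l_l_cm",
                   "w_h_px", "w_s_px")

#' Assemble the 13-element feature vector
#'
#' Fixed order: `[O_H, H_feat, T_feat, L_feat, W_feat, R_H, R_T, R_L,
#' L_H, L_T, L_L, W_H, W_S]`.
#'
#' @param o_h_cm metric height estimate.
#' @param densities output of [pixel_densities()].
#' @param w_feat output of [silhouette_size()].
#' @param ratios output of [weighted_ratios()].
#' @param lengths_cm output of [region_lengths_cm()].
#' @param widths_px output of [head_shoulder_widths()].
#' @return named numeric vector of length 13.
#' @export
assemble_features <- function(o_h_cm, densities, w_feat, ratios, lengths_cm,
                              widths_px) {
  v <- c(o_h_cm, densities, w_feat, ratios, lengths_cm, widths_px)
  if (length(v) != 13 || anyNA(v)) stopf("incomplete feature components")
  names(v) <- feature_names
  v
}

#' Compute the full 13-feature vector of one silhouette
#'
#' Per-frame driver chaining [extract_roi()], [estimate_height()],
#' [horizontal_projection()], [locate_regions()] and the individual feature
#' operations.
#'
#' @param mask cleaned 0/1 silhouette mask.
#' @param camera a [camera_geometry()].
#' @param roi optional precomputed `roi_bounds`.
#' @return named numeric vector of length 13.
#' @export
compute_features <- function(mask, camera, roi = NULL) {
  if (is.null(roi)) roi <- extract_roi(mask)
  est <- estimate_height(roi, camera)
  p_h <- horizontal_projection(mask, roi)
  seg <- locate_regions(p_h, roi)
  dens <- pixel_densities(mask, seg, roi)
  assemble_features(
    o_h_cm = est$o_h_cm,
    densities = dens,
    w_feat = silhouette_size(mask, roi),
    ratios = weighted_ratios(dens[1], dens[2], dens[3]),
    lengths_cm = region_lengths_cm(seg, roi, camera),
    widths_px = head_shoulder_widths(mask, seg, roi)
  )
}

#' Min-max feature normalization
#'
#' Fits per-feature minima/maxima on a training matrix and maps each feature
#' to `[0, 1]`; with supplied parameters, transforms new data and clips to
#' `[0, 1]` so test values outside the training envelope stay bounded.
#' A constant training feature (max = min) maps to 0.
#'
#' @param x numeric matrix (frames x 13 features).
#' @param params `NULL` to fit, or a previously returned `params` list with
#'   `min` and `max` vectors.
#' @return list with `features` (normalized matrix) and `params`.
#' @export
normalize_features <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (is.null(params)) {
    if (nrow(x) < 2) stopf("at least 2 vectors are needed to fit min/max")
    params <- list(min = apply(x, 2, min), max = apply(x, 2, max))
    fitted <- TRUE
  } else {
    fitted <- FALSE
  }
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  if (!fitted) out <- clamp(out, 0, 1)
  list(features = out, params = params)
}
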