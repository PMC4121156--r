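# Single-view metrology: upright height from ROI bounds via the cross-ratio
# with the camera height as the only reference length.

#' Estimate upright height from ROI bounds
#'
#' For a level camera the cross-ratio between the subject's top/bottom image
#' rows, the horizon row Y and the camera height H_c reduces to
#' `O_H = H_c * |X_T - X_B| / V` with `V = X_B - Y`. Rows increase downward,
#' so the subject's feet must project below the horizon.
#'
#' @param roi a `roi_bounds` object (or list with `top_row`, `bottom_row`).
#' @param camera a [camera_geometry()] object (uses `camera_height_cm` and
#'   `horizon_row_px`).
#' @param frame_index optional frame label carried through.
#' @return An object of class `height_estimate`: list with `o_h_cm`, `v_px`,
#'   `frame_index`.
#' @export
estimate_height <- function(roi, camera, frame_index = NA_integer_) {
  v <- roi$bottom_row - camera$horizon_row_px
  if (v <= 0) {
    stopf("subject bottom row (%s) is not below the horizon row (%s)",
          roi$bottom_row, camera$horizon_row_px)
  }
  o_h <- camera$camera_height_cm * abs(roi$top_row - roi$bottom_row) / v
  structure(list(o_h_cm = o_h, v_px = v, frame_index = frame_index),
            class = "height_estimate")
}

#' @export
print.height_estimate <- function(x, ...) {
  cat(sprintf("Height estimate: %.1f cm (V = %s px)\n", x$o_h_cm, x$v_px))
  invisible(x)
}

#' Calibrate the horizon row from reference observations
#'
#' Inverts the metrology equation for each reference object of known height
#' standing on the ground plane, `Y = X_B - H_c * (X_B - X_T) / H_ref`, and
#' averages the solutions. Used when the horizon row is not configured.
#'
#' @param reference_rois list of `roi_bounds`.
#' @param reference_heights_cm known heights of the references, cm.
#' @param camera_height_cm the reference camera height H_c, cm.
#' @return horizon row (numeric, may be fractional).
#' @export
calibrate_horizon <- function(reference_rois, reference_heights_cm,
                              camera_height_cm) {
  if (length(reference_rois) == 0) stopf("at least one reference is required")
  if (length(reference_rois) != length(reference_heights_cm)) {
    stopf("one reference height per ROI is required")
  }
  ys <- mapply(function(roi, h) {
    roi$bottom_row - camera_height_cm * (roi$bottom_row - roi$top_row) / h
  }, reference_rois, reference_heights_cm)
  mean(ys)
}

#' Per-subject height statistics over a frame sequence
#'
#' Errors in single frames are compensated across the sequence: the report
#' carries the mean estimate, the mean absolute error against the true
#' height, and the standard deviation of the per-frame absolute errors.
#'
#' @param estimates list of `height_estimate` objects or numeric vector of
#'   per-frame estimates (cm).
#' @param true_height_cm ground-truth stature, cm.
#' @param subject_id optional identifier carried through.
#' @return list with `subject_id`, `mean_est_cm`, `mae_cm`, `std_cm`,
#'   `n_frames`.
#' @export
subject_height_stats <- function(estimates, true_height_cm,
                                 subject_id = NA_character_) {
  est <- if (is.numeric(estimates)) {
    estimates
  } else {
    vapply(estimates, function(e) e$o_h_cm, numeric(1))
  }
  if (length(est) == 0) stopf("at least one estimate is required")
  abs_err <- abs(est - true_height_cm)
  list(
    subject_id = subject_id,
    mean_est_cm = mean(est),
    mae_cm = mean(abs_err),
    std_cm = if (length(abs_err) > 1) sd(abs_err) else 0,
    n_frames = length(est)
  )
}
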