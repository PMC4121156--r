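# Rank-k identification from the two-trait (height, weight) descriptor:
# z-score-normalized nearest-neighbour matching and CMC curves.

#' Build a gallery from enrolled estimates
#'
#' @param subject_id,height_cm,weight_kg vectors of equal length, one entry
#'   per subject.
#' @return data.frame of class `gallery` with one row per subject.
#' @export
make_gallery <- function(subject_id, height_cm, weight_kg) {
  if (anyDuplicated(subject_id)) stopf("one gallery entry per subject")
  structure(data.frame(subject_id = as.character(subject_id),
                       height_cm = height_cm, weight_kg = weight_kg,
                       stringsAsFactors = FALSE),
            class = c("gallery", "data.frame"))
}

gallery_scale <- function(gallery) {
  sdh <- sd(gallery$height_cm)
  sdw <- sd(gallery$weight_kg)
  list(center = c(mean(gallery$height_cm), mean(gallery$weight_kg)),
       sd = c(if (is.na(sdh) || sdh == 0) 1 else sdh,
              if (is.na(sdw) || sdw == 0) 1 else sdw))
}

#' Rank gallery subjects by similarity to a probe
#'
#' Distance is Euclidean over z-score-normalized (height, weight); the
#' normalization is fitted on the gallery unless `scale` is supplied. Ties
#' are broken by gallery order, so the ranking is deterministic.
#'
#' @param probe numeric vector `c(height_cm, weight_kg)`.
#' @param gallery a [make_gallery()] data.frame.
#' @param scale optional list with `center` and `sd` (length-2 each).
#' @return data.frame `subject_id`, `distance` sorted by ascending distance.
#' @export
match_rank <- function(probe, gallery, scale = NULL) {
  if (nrow(gallery) == 0) stopf("empty gallery")
  if (is.null(scale)) scale <- gallery_scale(gallery)
  zh <- (gallery$height_cm - scale$center[1]) / scale$sd[1]
  zw <- (gallery$weight_kg - scale$center[2]) / scale$sd[2]
  ph <- (probe[1] - scale$center[1]) / scale$sd[1]
  pw <- (probe[2] - scale$center[2]) / scale$sd[2]
  d <- sqrt((zh - ph)^2 + (zw - pw)^2)
  ord <- order(d, seq_len(nrow(gallery)))
  data.frame(subject_id = gallery$subject_id[ord], distance = d[ord],
             stringsAsFactors = FALSE)
}

#' Cumulative match characteristic curve
#'
#' `rate(k)` is the fraction of probes whose true identity appears within
#' the top k ranked gallery entries. The curve is non-decreasing and reaches
#' 1 at rank equal to the gallery size.
#'
#' @param probes data.frame with columns `subject_id`, `height_cm`,
#'   `weight_kg` (one row per probe; ids must exist in the gallery).
#' @param gallery a [make_gallery()] data.frame.
#' @param scale optional normalization, see [match_rank()].
#' @return numeric vector of class `cmc_curve`, identification rate at ranks
#'   `1..nrow(gallery)`.
#' @export
cmc_curve <- function(probes, gallery, scale = NULL) {
  if (!all(probes$subject_id %in% gallery$subject_id)) {
    stopf("every probe id must be present in the gallery")
  }
  if (is.null(scale)) scale <- gallery_scale(gallery)
  G <- nrow(gallery)
  ranks <- vapply(seq_len(nrow(probes)), function(i) {
    ranked <- match_rank(c(probes$height_cm[i], probes$weight_kg[i]),
                         gallery, scale)
    match(probes$subject_id[i], ranked$subject_id)
  }, integer(1))
  rates <- cumsum(tabulate(ranks, nbins = G)) / nrow(probes)
  structure(rates, class = "cmc_curve")
}

#' @export
print.cmc_curve <- function(x, ...) {
  r <- unclass(x)
  cat(sprintf("CMC over %d ranks: rank-1 %.1f%%, rank-5 %.1f%%, rank-%d 100%%\n",
              length(r), 100 * r[1], 100 * r[min(5, length(r))], length(r)))
  invisible(x)
}
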