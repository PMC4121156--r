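# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops) so they stay independent of the
# vectorized implementations they check.

default_camera <- function() camera_geometry()

default_body <- function(height_cm = 175, ...) {
  body_params("T01", height_cm = height_cm, mass_kg = 70, ...)
}

random_rgb_pair <- function(h = 12, w = 9) {
  list(bg = array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)),
       fr = array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

random_mask <- function(h = 20, w = 15, p = 0.4) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# Eq (1) by three explicit loops over pixels and bands.
oracle_rgb_difference <- function(bg, fr) {
  D <- matrix(0, dim(bg)[1], dim(bg)[2])
  for (i in seq_len(dim(bg)[1])) {
    for (j in seq_len(dim(bg)[2])) {
      for (b in 1:3) D[i, j] <- D[i, j] + (bg[i, j, b] - fr[i, j, b])^2
    }
  }
  D
}

# Otsu by exhaustive search over all 256 candidate levels.
oracle_otsu <- function(levels) {
  v <- as.vector(levels)
  best <- -Inf
  best_k <- 0L
  for (k in 0:255) {
    c0 <- v[v <= k]
    c1 <- v[v > k]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / length(v)
    w1 <- 1 - w0
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best) {           # strict: ties keep the smallest level
      best <- s
      best_k <- k
    }
  }
  best_k
}

# Horizontal projection by a double loop.
oracle_projection <- function(mask, rows) {
  p <- integer(length(rows))
  for (a in seq_along(rows)) {
    for (j in seq_len(ncol(mask))) {
      if (mask[rows[a], j] == 1) p[a] <- p[a] + 1
    }
  }
  p
}

# One mask-only rendered frame of the default subject.
gt_frame <- function(height_cm = 175, seed = 7, n = 1, ...) {
  sq <- render_sequence(default_body(height_cm, ...), default_camera(), n,
                        seed = seed, rgb = FALSE)
  if (n == 1) sq$frames[[1]] else sq$frames
}
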