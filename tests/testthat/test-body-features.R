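# 13-feature measurement stage: projections, region segmentation,
# densities, ratios, metric lengths, widths, normalization.

test_that("horizontal projection equals the double-loop count", {
  full <- matrix(1L, 5, 4)
  expect_equal(as.integer(horizontal_projection(
    full, list(top_row = 1, bottom_row = 5))), rep(4L, 5))
  m <- matrix(0L, 8, 6)
  m[2, ] <- 1L
  p <- horizontal_projection(m, list(top_row = 1, bottom_row = 8))
  expect_equal(as.integer(p), c(0L, 6L, rep(0L, 6)))
  set.seed(12)
  for (i in 1:20) {
    rm <- random_mask()
    roi <- list(top_row = 3, bottom_row = 18)
    expect_equal(as.integer(horizontal_projection(rm, roi)),
                 oracle_projection(rm, 3:18))
  }
})

test_that("region boundaries sit at the projection minima with earliest ties", {
  # unique minima at 20% (neck) and 50% (waist) of a 100-row profile
  p <- rep(30L, 100)
  p[20] <- 5L
  p[50] <- 8L
  seg <- locate_regions(p, list(top_row = 1, bottom_row = 100))
  expect_equal(seg$head_boundary_row, 20)
  expect_equal(seg$torso_boundary_row, 50)
  expect_equal(seg$l_hp + seg$l_tp + seg$l_lp, 100)
  # ties at 15% and 25% -> earliest row
  p2 <- rep(30L, 100)
  p2[c(15, 25)] <- 5L
  seg2 <- locate_regions(p2, list(top_row = 1, bottom_row = 100))
  expect_equal(seg2$head_boundary_row, 15)
  expect_error(locate_regions(rep(3L, 9)), "10 rows")
})

test_that("segmentation recovers the generator's region boundaries", {
  cam <- default_camera()
  for (seed in c(3, 14)) {
    fr <- gt_frame(seed = seed)
    roi <- extract_roi(fr$gt_mask)
    seg <- locate_regions(horizontal_projection(fr$gt_mask, roi), roi)
    I <- roi$bottom_row - roi$top_row + 1
    expect_lte(abs(seg$head_boundary_row - (roi$top_row + 0.15 * I)), 2.5)
    expect_lte(abs(seg$torso_boundary_row - (roi$top_row + 0.50 * I)), 2.5)
  }
})

test_that("pixel densities and silhouette size match naive recomputation", {
  m <- matrix(0L, 40, 30)
  m[1:40, 11:20] <- 1L                  # uniform 10-px-wide column
  roi <- list(top_row = 1, bottom_row = 40)
  seg <- list(head_boundary_row = 8, torso_boundary_row = 24,
              l_hp = 8, l_tp = 16, l_lp = 16)
  d <- pixel_densities(m, seg, roi)
  expect_equal(unname(d), c(10, 10, 10))
  expect_equal(silhouette_size(m, roi), 400 / 39)
  set.seed(21)
  for (i in 1:20) {
    rm <- random_mask(40, 30)
    dd <- pixel_densities(rm, seg, roi)
    expect_equal(unname(dd[1]), sum(rm[1:8, ]) / 8)
    expect_equal(unname(dd[2]), sum(rm[9:24, ]) / 16)
    expect_equal(unname(dd[3]), sum(rm[25:40, ]) / 16)
    expect_equal(silhouette_size(rm, roi), sum(rm) / 39)
  }
  # doubling the mask width doubles the size feature
  m2 <- matrix(0L, 40, 30)
  m2[1:40, 6:25] <- 1L
  expect_equal(silhouette_size(m2, roi), 2 * silhouette_size(m, roi))
})

test_that("weighted ratios follow Eq substitution, symmetry, homogeneity", {
  r <- weighted_ratios(1, 2, 3)
  expect_equal(unname(r), c(0.2, 1.0, 3.0))
  r_sym <- weighted_ratios(4, 4, 4)
  expect_equal(unname(r_sym), rep(2, 3))          # d/2 each
  s <- 3.7
  expect_equal(unname(weighted_ratios(1 * s, 2 * s, 3 * s)),
               s * unname(weighted_ratios(1, 2, 3)))
  expect_error(weighted_ratios(0, 0, 5), "denominator")
})

test_that("metric region lengths follow the printed cumulative formula", {
  cam <- camera_geometry(camera_height_cm = 120, horizon_row_px = 100)
  # H_c / V = 1 requires V = 120 px: bottom 220, ROI height 150 -> top 70
  roi <- list(top_row = 70, bottom_row = 220)
  seg <- list(l_hp = 50, l_tp = 50, l_lp = 50)
  len <- region_lengths_cm(seg, roi, cam)
  expect_equal(unname(len), c(50, 100, 50))
  est <- estimate_height(roi, cam)
  expect_equal(unname(len["l_h_cm"] + len["l_t_cm"]), est$o_h_cm)
  # L_LP = 0 -> zero leg length
  len0 <- region_lengths_cm(list(l_hp = 50, l_tp = 100, l_lp = 0), roi, cam)
  expect_equal(unname(len0["l_l_cm"]), 0)
})

test_that("head and shoulder widths match rectangles and the generator", {
  m <- matrix(0L, 60, 50)
  m[1:12, 20:31] <- 1L                   # head 12 px wide
  m[13, 23:28] <- 1L                     # neck notch
  m[14:40, 11:40] <- 1L                  # torso 30 px wide
  m[41, 22:29] <- 1L                     # waist notch
  m[42:60, 16:35] <- 1L                  # legs
  roi <- list(top_row = 1, bottom_row = 60)
  seg <- locate_regions(horizontal_projection(m, roi), roi)
  w <- head_shoulder_widths(m, seg, roi)
  expect_equal(unname(w["w_h_px"]), 12)
  expect_equal(unname(w["w_s_px"]), 30)
  cam <- default_camera()
  fr <- gt_frame(seed = 28)
  roi <- extract_roi(fr$gt_mask)
  seg <- locate_regions(horizontal_projection(fr$gt_mask, roi), roi)
  w <- head_shoulder_widths(fr$gt_mask, seg, roi)
  s <- cam$focal_px / cam$subject_distance_cm
  expect_lte(abs(w["w_h_px"] - 15 * s), 2)
  expect_lte(abs(w["w_s_px"] - 44 * s), 2)
})

test_that("assembled vectors always have 13 elements and the length identity", {
  cam <- default_camera()
  frames <- gt_frame(seed = 33, n = 3)
  vs <- lapply(frames, function(fr) compute_features(fr$gt_mask, cam))
  for (v in vs) {
    expect_length(v, 13)
    expect_true(all(v >= 0))
    expect_equal(unname(v["l_h_cm"] + v["l_t_cm"]), unname(v["o_h_cm"]),
                 tolerance = 1e-12)
  }
  # identical frames give identical vectors
  expect_identical(compute_features(frames[[1]]$gt_mask, cam),
                   compute_features(frames[[1]]$gt_mask, cam))
  expect_error(assemble_features(170, c(1, 2), 3, c(4, 5, 6),
                                 c(7, 8, 9), c(10, 11)), "incomplete")
})

test_that("min-max normalization maps, clips and handles constants", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  nz <- normalize_features(x)
  expect_equal(unname(nz$features[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nz$features[, 2]), c(0, 0, 0))   # constant -> 0
  tr <- normalize_features(cbind(a = c(1, 7), b = c(5, 5)), nz$params)
  expect_equal(unname(tr$features[, 1]), c(0, 1))      # clipped to [0, 1]
  set.seed(2)
  big <- matrix(rnorm(50 * 13), 50, 13)
  nb <- normalize_features(big)
  expect_true(all(nb$features >= 0 & nb$features <= 1))
  expect_error(normalize_features(matrix(1, 1, 13)), "2 vectors")
})
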