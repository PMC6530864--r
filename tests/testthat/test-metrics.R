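test_that("separation angle matches coordinate-geometry cases", {
  expect_equal(separation_angle(4, 4, c(1, 1)), pi / 4)
  expect_equal(separation_angle(5.5, 0.5, c(0.5, 0.5)), 0)
  expect_equal(separation_angle(3, 4, c(0, 0)), atan(4 / 3))
  expect_equal(separation_angle(0, 5, c(0, 0)), pi / 2)  # on-axis A22
  ntc <- structure(list(centroid = c(1, 2), spread = 0, n_ntc = 1L),
                   class = "ntc_reference")
  expect_equal(separation_angle(4, 6, ntc), atan(4 / 3))
  expect_error(separation_angle(1, 2, ntc), "coincides")
})

test_that("atan2 angle equals the plain arctangent whenever dx > 0", {
  set.seed(31)
  n <- 1000
  ntc <- c(0.4, 0.3)
  x <- runif(n, ntc[1] + 1e-6, 6)
  y <- runif(n, ntc[2], 6)
  a <- separation_angle(x, y, ntc)
  oracle <- atan((y - ntc[2]) / (x - ntc[1]))  # brute-force formula
  expect_equal(a, pmin(pmax(oracle, 0), pi / 2), tolerance = 1e-14)
})

test_that("NTC distance is the Euclidean norm of the deltas", {
  expect_equal(ntc_distance(3, 4, c(0, 0)), 5)
  expect_equal(ntc_distance(1, 2, c(1, 2)), 0)
  expect_equal(ntc_distance(4, 6, c(1, 2)), 5)
})

test_that("compactness is the sample SD of point-to-centroid distances", {
  # equidistant ring: all distances 1, SD 0
  expect_equal(compactness(c(0, 0, 1, -1), c(1, -1, 0, 0)), 0)
  # hand oracle: centroid (0,0), d = {2, 2, 0}, sd = sqrt(8/3 - ...) =
  # sqrt(sum((d - 4/3)^2) / 2) = sqrt(4/3)
  expect_equal(compactness(c(2, -2, 0), c(0, 0, 0)), sqrt(4 / 3))
  expect_equal(compactness(c(5, 5, 5), c(2, 2, 2)), 0)  # degenerate
  expect_identical(compactness(1, 1), NA_real_)          # n < 2
})

test_that("angle is scale-free; distance and compactness scale linearly", {
  set.seed(41)
  n <- 50
  x <- runif(n, 1, 5); y <- runif(n, 1, 5); ntc <- c(0.5, 0.7)
  for (c_scale in c(0.2, 3, 120)) {
    expect_equal(separation_angle(c_scale * x, c_scale * y,
                                  c_scale * ntc),
                 separation_angle(x, y, ntc), tolerance = 1e-12)
    expect_equal(ntc_distance(c_scale * x, c_scale * y, c_scale * ntc),
                 c_scale * ntc_distance(x, y, ntc), tolerance = 1e-12)
    expect_equal(compactness(c_scale * x, c_scale * y),
                 c_scale * compactness(x, y), tolerance = 1e-12)
  }
  # translation of points and NTC together changes nothing
  sh <- c(-2.5, 11)
  expect_equal(separation_angle(x + sh[1], y + sh[2], ntc + sh),
               separation_angle(x, y, ntc), tolerance = 1e-12)
  expect_equal(ntc_distance(x + sh[1], y + sh[2], ntc + sh),
               ntc_distance(x, y, ntc), tolerance = 1e-12)
  expect_equal(compactness(x + sh[1], y + sh[2]), compactness(x, y),
               tolerance = 1e-9)
})

test_that("cluster summaries match hand-computed values on a fixture", {
  # one assay, four hand-placed points per genotype label, two NTCs
  ntc_xy <- rbind(c(0.9, 1.1), c(1.1, 0.9))           # centroid (1, 1)
  a11 <- rbind(c(4, 1.5), c(4.2, 1.7), c(3.8, 1.3), c(4.0, 1.9))
  a12 <- rbind(c(3, 3), c(3.2, 3.2), c(2.8, 2.8), c(3.1, 2.9))
  a22 <- rbind(c(1.5, 4), c(1.7, 4.2), c(1.3, 3.8), c(1.9, 4.0))
  xy <- rbind(a11, a12, a22, ntc_xy)
  pts <- data.frame(
    well_id = sprintf("A%02d", 1:14),
    sample_id = c(sprintf("S%02d", 1:12), "NTC", "NTC"),
    assay_id = "A1", platform_id = "p",
    signal_x = xy[, 1], signal_y = xy[, 2],
    is_ntc = c(rep(FALSE, 12), TRUE, TRUE), stringsAsFactors = FALSE)
  calls <- data.frame(
    sample_id = pts$sample_id, assay_id = "A1", platform_id = "p",
    label = c(rep(c("A11", "A12", "A22"), each = 4), "NTC", "NTC"),
    quality = c(rep(1, 12), NA, NA), stringsAsFactors = FALSE)

  # spreadsheet-style oracle for the A11 cluster, written out longhand
  cen <- colMeans(a11)
  d_cen <- sqrt(sum((cen - c(1, 1))^2))
  ang_cen <- atan((cen[2] - 1) / (cen[1] - 1))
  d_i <- sqrt((a11[, 1] - cen[1])^2 + (a11[, 2] - cen[2])^2)
  comp <- sqrt(sum((d_i - mean(d_i))^2) / 3)

  s <- summarize_clusters(pts, calls, unit = "per_cluster")
  expect_identical(nrow(s), 3L)
  r <- s[s$label == "A11", ]
  expect_equal(c(r$centroid_x, r$centroid_y), unname(cen))
  expect_equal(r$mean_angle, unname(ang_cen))
  expect_equal(r$mean_ntc_distance, d_cen)
  expect_equal(r$compactness, comp)
  expect_identical(r$n, 4L)

  # per-point aggregation averages the pointwise values instead
  sp <- summarize_clusters(pts, calls, unit = "per_point")
  rp <- sp[sp$label == "A11", ]
  ang_i <- atan((a11[, 2] - 1) / (a11[, 1] - 1))
  dd_i <- sqrt((a11[, 1] - 1)^2 + (a11[, 2] - 1)^2)
  expect_equal(rp$mean_angle, mean(ang_i))
  expect_equal(rp$mean_ntc_distance, mean(dd_i))
  expect_equal(rp$compactness, r$compactness)  # unit-independent

  # A11-only view keeps exactly one row per assay x platform
  expect_identical(nrow(summarize_clusters(pts, calls,
                                           a11_only = TRUE)), 1L)
})

test_that("noiseless summaries recover planted geometry exactly", {
  cfg <- noiseless_config(seed = 10)
  p <- cfg$platforms[[1]]
  exp <- simulate_experiment(cfg)
  s <- summarize_clusters(exp$points, truth_calls(exp, "pure"),
                          a11_only = TRUE)
  expect_equal(s$mean_angle, rep(p$angle_a11, nrow(s)),
               tolerance = 1e-12)
  expect_equal(s$mean_ntc_distance, rep(p$gain, nrow(s)),
               tolerance = 1e-12)
  expect_equal(s$compactness, rep(0, nrow(s)), tolerance = 1e-12)
})

test_that("planted geometric contrasts propagate through the pipeline", {
  # platform alpha: smaller A11 angle, larger gain than beta
  pa <- platform_profile("big", gain = 4, angle_a11 = 0.18,
                         angle_a22 = 1.35, noise_sd = 0.12,
                         ntc_center = c(0.3, 0.3), ntc_sd = 0.05)
  pb <- platform_profile("small", gain = 1.6, angle_a11 = 0.33,
                         angle_a22 = 1.22, noise_sd = 0.08,
                         ntc_center = c(0.25, 0.25), ntc_sd = 0.025)
  cfg <- sim_config(list(pa, pb), n_samples = 60, n_ntc = 2,
                    n_assays = 6, maf = 0.35, seed = 14)
  exp <- simulate_experiment(cfg)
  calls <- call_plate(exp$points)
  s <- summarize_clusters(exp$points, calls, a11_only = TRUE)
  m_ang <- tapply(s$mean_angle, s$platform_id, mean)
  m_dist <- tapply(s$mean_ntc_distance, s$platform_id, mean)
  expect_lt(m_ang[["big"]], m_ang[["small"]])
  expect_gt(m_dist[["big"]], m_dist[["small"]])
})
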