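# Generators must be deterministic under (params, seed) and every realized
# ground-truth entry must be recoverable by recounting the emitted artifact.

test_that("generators are bit-identical under identical params and seed", {
  a <- make_condensate_cell(4, snr_target = 0.4, seed = 7)
  b <- make_condensate_cell(4, snr_target = 0.4, seed = 7)
  expect_identical(a$channel1$pixels, b$channel1$pixels)
  expect_identical(a$ground_truth$realized, b$ground_truth$realized)
  expect_false(identical(
    a$channel1$pixels,
    make_condensate_cell(4, snr_target = 0.4, seed = 8)$channel1$pixels
  ))

  t1 <- make_trajectory(20, seed = 3)$trajectory
  t2 <- make_trajectory(20, seed = 3)$trajectory
  expect_identical(t1, t2)

  f1 <- make_frap_curve(0.2, 0.8, 0.05, noise_sd = 0.02, seed = 5)$curve
  f2 <- make_frap_curve(0.2, 0.8, 0.05, noise_sd = 0.02, seed = 5)$curve
  expect_identical(f1, f2)
})

test_that("condensate-cell in-spot fraction matches a pixel-sum recount", {
  sim <- make_condensate_cell(5, snr_target = 0.5, seed = 1)
  px <- sim$channel1$pixels
  gt <- sim$ground_truth$realized
  rr <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
  cc <- matrix(seq_len(ncol(px)), nrow(px), ncol(px), byrow = TRUE)
  roi <- matrix(FALSE, nrow(px), ncol(px))
  for (i in seq_len(nrow(gt$centers))) {
    roi <- roi | ((rr - gt$centers[i, 1])^2 + (cc - gt$centers[i, 2])^2 <=
                    gt$roi_radius_px^2)
  }
  recount <- sum(px[roi]) / sum(px)
  expect_equal(recount, gt$in_spot_fraction, tolerance = 1e-12)
  expect_lt(abs(recount - 0.5), 0.02)
})

test_that("condensate-cell degenerate cases behave as specified", {
  blank <- make_condensate_cell(0, background = 7, seed = 1)
  expect_true(all(blank$channel1$pixels == 7))
  expect_equal(blank$ground_truth$realized$in_spot_fraction, 0)

  dark <- make_condensate_cell(5, background = 0, spot_amplitude = 50, seed = 2)
  expect_equal(dark$ground_truth$realized$in_spot_fraction, 1, tolerance = 1e-6)

  expect_error(make_condensate_cell(500, seed = 1), "placement")
})

test_that("population realized counts match the emitted records", {
  pop <- make_population(200, 0.3, seed = 11)
  expect_equal(sum(pop$records$colocalized_positive),
               pop$ground_truth$realized$n_positive)
  expect_true(all(is.na(pop$records$snr[!pop$records$colocalized_positive])))
  expect_true(all(pop$records$snr[pop$records$colocalized_positive] >= 0 &
                  pop$records$snr[pop$records$colocalized_positive] <= 1))
  expect_equal(sum(make_population(50, 0, seed = 1)$records$colocalized_positive), 0)
  expect_true(all(make_population(50, 1, seed = 1)$records$colocalized_positive))
})

test_that("realized positive frequency converges to the nominal rate", {
  pop <- make_population(10000, 0.3, seed = 42)
  k <- pop$ground_truth$realized$n_positive
  ci <- stats::binom.test(k, 10000, 0.3)$p.value
  expect_gt(ci, 0.001)  # realized count consistent with Binomial(10000, 0.3)
})

test_that("fiber ground truth matches a recount of the drawn mask", {
  fib <- make_fiber_image(30, length_px = 30, width_px = 3, seed = 4)
  obj <- fib$ground_truth$realized$objects
  expect_equal(obj$area_px, 90, tolerance = 0.1)  # ~L*W pixels
  expect_equal(obj$aspect_ratio, 10, tolerance = 0.15)
  empty <- make_fiber_image(numeric(0), seed = 1)
  expect_true(all(empty$image$pixels == 0))
})

test_that("straight trajectories have unit directionality and exact speed", {
  tr <- make_trajectory(20, step_len_um = 1, turn_sd_deg = 0, dt_min = 1,
                        seed = 9)$trajectory
  ps <- path_stats(tr)
  expect_equal(ps$directionality, 1, tolerance = 1e-12)
  expect_equal(ps$speed, 1, tolerance = 1e-12)
})

test_that("trajectory lag-1 cosine matches the wrapped-normal closed form", {
  sigma <- 30
  tr <- make_trajectory(5000, turn_sd_deg = sigma, seed = 13)$trajectory
  ac <- direction_autocorrelation(tr, max_lag_min = 10, dt_min = 10)
  expected <- exp(-deg2rad_test(sigma)^2 / 2)
  # Monte-Carlo SE of the mean cosine
  dx <- diff(tr$x_um); dy <- diff(tr$y_um)
  cosv <- (dx[-length(dx)] * dx[-1] + dy[-length(dy)] * dy[-1]) /
    (sqrt(dx[-length(dx)]^2 + dy[-length(dy)]^2) * sqrt(dx[-1]^2 + dy[-1]^2))
  se <- stats::sd(cosv) / sqrt(length(cosv))
  expect_lt(abs(ac$mean_cos[2] - expected), 3 * se)
})

test_that("moving-mask centroids follow the programmed drift", {
  mv <- make_moving_mask(6, base_radius_px = 25, drift_px_per_frame = c(1, 0),
                         seed = 2)
  cent <- mv$ground_truth$realized$centroids
  expect_equal(diff(cent[, "x"]), rep(1, 5), tolerance = 0.05)
  expect_equal(diff(cent[, "y"]), rep(0, 5), tolerance = 0.05)
  still <- make_moving_mask(3, seed = 1)
  expect_identical(still$masks[, , 1], still$masks[, , 3])
  expect_error(
    make_moving_mask(5, base_radius_px = 60, drift_px_per_frame = c(20, 0),
                     shape = c(128, 128), seed = 1),
    "border"
  )
})

test_that("puncta ground-truth band flags equal manual filter application", {
  p <- data.frame(area_um2 = c(2, 40, 5, 0.1, 3),
                  peak_intensity = c(2000, 2000, 5000, 2000, 1000))
  sim <- make_puncta_image(p, seed = 3)
  obj <- sim$ground_truth$realized$objects
  manual <- obj$peak_intensity >= 1200 & obj$peak_intensity <= 4500 &
    obj$area_um2 >= 0.5 & obj$area_um2 <= 15
  expect_identical(obj$in_band, manual)
  expect_equal(sim$ground_truth$realized$n_in_band, sum(manual))
  empty <- make_puncta_image(data.frame(area_um2 = numeric(0),
                                        peak_intensity = numeric(0)), seed = 1)
  expect_true(all(empty$image$pixels == 100))
})

test_that("frap curve evaluates the closed form exactly", {
  fr <- make_frap_curve(0.2, 0.8, 0.05, t = c(0, log(2) / 0.05, 1000),
                        seed = 1)
  post <- fr$curve[fr$curve$phase == "post", ]
  expect_equal(post$value[1], 0.2, tolerance = 1e-12)
  expect_equal(post$value[2], 0.5, tolerance = 1e-12)  # half recovery at ln2/k
  expect_equal(post$value[3], 0.8, tolerance = 1e-10)
  expect_true(all(fr$curve$value[fr$curve$phase == "pre"] == 1))
})
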