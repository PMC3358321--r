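test_that("line voting matches a brute-force oracle and conserves votes", {
  set.seed(42)
  pts <- cbind(runif(37, 0, 100), runif(37, 0, 100))
  theta <- seq(-90, 89.5, by = 0.5)
  rho_axis <- seq(-142, 142, by = 2)
  acc <- line_transform(pts, theta, rho_axis)
  expect_equal(acc$votes, oracle_line_votes(pts, theta, rho_axis),
               ignore_attr = TRUE)
  expect_equal(sum(acc$votes), 37 * length(theta))
})

test_that("collinear points vote into a single consensus cell", {
  acc <- line_transform(rbind(c(30, 30), c(50, 50), c(70, 70)),
                        rho_axis = 1, dims = c(101, 101))
  expect_equal(max(acc$votes), 3)
  # a single point can never exceed one vote per cell
  one <- line_transform(rbind(c(50, 50)), rho_axis = 1, dims = c(101, 101))
  expect_equal(max(one$votes), 1)
  expect_error(line_transform(matrix(numeric(0), 0, 2)), "empty")
})

test_that("median smoothing suppresses isolated votes and keeps constants", {
  acc <- line_transform(rbind(c(10, 10)), rho_axis = 6, dims = c(64, 64))
  acc$votes <- matrix(5L, 31, 360)
  sm <- smooth_line_accumulator(acc, window = c(3, 3))
  expect_true(all(sm$votes[2:30, 2:359] == 5))
  acc$votes <- matrix(0L, 31, 360)
  acc$votes[15, 100] <- 1L
  sm <- smooth_line_accumulator(acc, window = c(3, 3))
  expect_equal(sm$votes[15, 100], 0)
  # default window: floor(dims / 75), forced odd
  big <- acc
  big$votes <- matrix(0L, 302, 360)
  expect_silent(smooth_line_accumulator(big))
  expect_error(smooth_line_accumulator(acc, window = c(100, 3)), "window")
})

test_that("detect_lines recovers a diagonal within one theta step", {
  pts <- cbind(0:99, 0:99)
  acc <- line_transform(pts, rho_axis = 6, dims = c(100, 100))
  cfg <- hough_params("line", min_line_length = 50, max_gap = 5)
  segs <- detect_lines(acc, pts, cfg)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$theta - (-45)), 0.5 + 1e-9)
  expect_gte(segs$length, 50)

  # empty accumulator -> empty result, not an error
  acc0 <- acc
  acc0$votes[] <- 0L
  expect_equal(nrow(detect_lines(acc0, pts, cfg)), 0)
})

test_that("parallel lines separated by >= 2 rho steps give two segments", {
  m <- make_parallel_line_mask(200, 200, n_lines = 2, spacing = 24,
                               theta = 30)
  pts <- m$active
  acc <- line_transform(pts, rho_axis = 6, dims = c(200, 200))
  cfg <- hough_params("line", min_line_length = 50, max_gap = 5,
                      peak_separation = c(2, 2))
  segs <- detect_lines(acc, pts, cfg)
  segs <- segs[order(-segs$votes), ][1:2, ]
  expect_equal(nrow(segs), 2)
  expect_lte(abs(segs$theta[1] - segs$theta[2]), 0.5 + 1e-9)
  expect_gte(abs(segs$rho[1] - segs$rho[2]), 12)
})

test_that("line peaks are robust to a minority of uniform outliers", {
  mask <- make_line_mask(300, 300, endpoints = rbind(c(10, 40, 290, 250)))
  locs <- sample_localizations(mask, 0.8, seed = 1)
  base_fit <- hough_fit(locs, "line", dims = c(300, 300),
                        params = hough_params("line", min_line_length = 80))
  noisy <- add_outlier_noise(locs, mask, 0.0005, seed = 2)  # ~45 outliers
  noisy_fit <- hough_fit(noisy, "line", dims = c(300, 300),
                         params = hough_params("line", min_line_length = 80))
  expect_gt(nrow(noisy_fit$detections), 0)
  expect_lte(abs(noisy_fit$detections$theta[1] - base_fit$detections$theta[1]),
             0.5 + 1e-9)
  expect_lte(abs(noisy_fit$detections$rho[1] - base_fit$detections$rho[1]),
             6 + 1e-9)
})

test_that("hough_fit model object exposes the standard methods", {
  mask <- make_line_mask(256, 256, 3, seed = 2)
  locs <- sample_localizations(mask, 0.5, seed = 3)
  fit <- hough_fit(locs, "line", dims = c(256, 256),
                   params = hough_params("line", min_line_length = 80))
  expect_s3_class(fit, "smlm_hough")
  expect_output(print(fit), "Hough line fit")
  expect_output(print(summary(fit)), "accumulator maximum")
  expect_equal(colnames(coef(fit)), c("rho", "theta"))
  res <- residuals(fit)
  expect_length(res, nrow(locs$points))
  expect_lt(median(res), 3 + 1e-9)  # most points near a fitted line
  pr <- predict(fit, newdata = locs$points[1:5, ])
  expect_equal(nrow(pr), 5)
  rec <- fitted(fit)
  expect_equal(dim(rec), c(256, 256))
  sim <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "localization_set")
  expect_identical(sim[[1]]$points,
                   simulate(fit, nsim = 2, seed = 4)[[1]]$points)
})
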