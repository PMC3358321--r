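test_that("circle voting conserves per-slice totals for interior points", {
  set.seed(7)
  pts <- cbind(runif(20, 90, 110), runif(20, 90, 110))
  r_axis <- c(10, 15, 20)
  acc <- circle_transform(pts, c(200, 200), r_axis)
  for (k in seq_along(r_axis)) {
    per <- nrow(cpp_circle_pixels(0, 0, r_axis[k]))
    expect_equal(sum(acc$votes[, , k]), 20 * per)
  }
})

test_that("points on a circle produce an exact consensus maximum", {
  for (n in c(5, 20)) {
    pts <- circle_perimeter_points(100, 100, 50, n)
    acc <- circle_transform(pts, c(201, 201), seq(40, 60, by = 1))
    expect_equal(max(acc$votes), n)
    w <- which(acc$votes == n, arr.ind = TRUE)
    expect_equal(unname(w[1, ]), c(101, 101, 11))  # centre (100,100), r 50
  }
  one <- circle_transform(rbind(c(100, 100)), c(201, 201), 50)
  expect_equal(max(one$votes), 1)
  expect_error(circle_transform(matrix(numeric(0), 0, 2), c(10, 10), 5),
               "empty")
})

test_that("LoG+unsharp smoothing keeps peaks in place (convolution oracle)", {
  vol <- array(0, dim = c(21, 21, 1))
  vol[11, 11, 1] <- 10
  acc <- structure(list(votes = vol, r = 5, dims = c(21, 21)),
                   class = "circle_accumulator")
  sm <- smooth_circle_accumulator(acc, log_sigma = 1.5, log_size = 9,
                                  unsharp_amount = 0.2)
  w <- which(sm$votes == max(sm$votes), arr.ind = TRUE)
  expect_lte(max(abs(w[1, 1:2] - c(11, 11))), 4)

  # FFT path agrees with a direct spatial convolution oracle
  k <- -smlmhough:::log_kernel(1.5, 9)
  direct <- oracle_conv2(vol[, , 1], k)
  viafft <- smlmhough:::conv2_fft(vol[, , 1], k)
  expect_equal(viafft, direct, tolerance = 1e-10)

  # constant volume stays constant away from the boundary
  acc$votes <- array(3, dim = c(21, 21, 1))
  smc <- smooth_circle_accumulator(acc, log_sigma = 1.5, log_size = 9)
  inner <- smc$votes[7:15, 7:15, 1]
  expect_lt(diff(range(inner)), 1e-8)
  expect_error(smooth_circle_accumulator(acc, log_sigma = 10), "kernel")
})

test_that("detect_circles finds the noiseless circle exactly", {
  pts <- circle_perimeter_points(100, 100, 50, 20)
  acc <- circle_transform(pts, c(201, 201), seq(40, 60, by = 1))
  det <- detect_circles(acc, hough_params("circle", r_range = c(40, 60)))
  expect_equal(nrow(det), 1)
  expect_equal(unname(unlist(det[1, c("a", "b", "r")])), c(100, 100, 50))
  expect_equal(det$votes[1], 20)
  expect_equal(det$diameter_nm[1], 100)
})

test_that("suppression keeps one of two close equal peaks, by lower index", {
  vol <- array(0, dim = c(100, 100, 3))
  vol[30, 30, 2] <- 5; vol[40, 40, 2] <- 5   # 14 px apart, equal score
  vol[80, 80, 2] <- 4
  acc <- structure(list(votes = vol, r = c(10, 11, 12), dims = c(100, 100)),
                   class = "circle_accumulator")
  cfg <- hough_params("circle", peak_threshold_frac = 0.5,
                      min_spatial_sep = 20, min_radius_sep = 75)
  det <- detect_circles(acc, cfg)
  expect_equal(nrow(det), 2)
  expect_equal(det$a[1], 29)  # lexicographically lower of the tied pair
  expect_equal(det$b[1], 29)

  # max_peaks truncates to the highest-vote circles (brute-force order)
  cfg2 <- hough_params("circle", peak_threshold_frac = 0.5,
                       min_spatial_sep = 20, min_radius_sep = 75,
                       max_peaks = 2)
  det2 <- detect_circles(acc, cfg2)
  expect_equal(nrow(det2), 2)
  expect_equal(det2$votes, c(5, 4))
})

test_that("known-radius 2-d search equals the matching 3-d slice", {
  pts <- circle_perimeter_points(60, 60, 25, 15)
  full <- circle_transform(pts, c(121, 121), seq(20, 30, by = 1))
  slice <- circle_transform(pts, c(121, 121), 25)
  expect_equal(slice$votes[, , 1], full$votes[, , 6])
})

test_that("circle peaks are robust to outliers and to line cross-talk", {
  mask <- make_circle_mask(300, 300, circles = rbind(c(150, 150, 45)))
  locs <- sample_localizations(mask, 0.5, seed = 1)
  params <- hough_params("circle", r_range = c(35, 55))
  base <- hough_fit(locs, "circle", dims = c(300, 300), params = params)
  expect_equal(unname(unlist(base$detections[1, c("a", "b", "r")])),
               c(150, 150, 45))

  # outliers: k = 45 uniform spurious points vs n = 141 structured
  noisy <- add_outlier_noise(locs, mask, 0.0005, seed = 2)
  nf <- hough_fit(noisy, "circle", dims = c(300, 300), params = params)
  expect_lte(max(abs(unlist(nf$detections[1, c("a", "b", "r")]) -
                       c(150, 150, 45))), 1)

  # cross-talk: add a line's points; circle detection is unmoved and no
  # circle is detected sitting on the line
  lmask <- make_line_mask(300, 300, endpoints = rbind(c(5, 280, 295, 20)))
  lpts <- sample_localizations(lmask, 0.5, seed = 3)
  mixed <- rbind(as.matrix(locs$points), as.matrix(lpts$points))
  mf <- hough_fit(mixed, "circle", dims = c(300, 300), params = params)
  expect_lte(max(abs(unlist(mf$detections[1, c("a", "b", "r")]) -
                       c(150, 150, 45))), 1)
  if (nrow(mf$detections) > 1) {
    th <- lmask$shapes[[1]]$theta * pi / 180
    dline <- abs(mf$detections$a * cos(th) + mf$detections$b * sin(th) -
                   lmask$shapes[[1]]$rho)
    expect_true(all(dline[-1] > 10))
  }
})
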