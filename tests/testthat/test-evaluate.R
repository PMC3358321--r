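test_that("render_shapes reproduces masks through the shared rasterizer", {
  mask <- make_circle_mask(200, 200, circles = rbind(c(100, 100, 50),
                                                     c(40, 40, 20)))
  expect_equal(render_shapes(mask$shapes, 200, 200), mask_image(mask))
  expect_equal(render_shapes(list(), 64, 64), matrix(0, 64, 64))
  img <- render_shapes(list(circle_shape(100, 100, 50)), 201, 201)
  expect_equal(sum(img), nrow(cpp_circle_pixels(100, 100, 50)))
  expect_error(render_shapes(list(circle_shape(10, 10, 50)), 64, 64),
               "frame")
  expect_silent(render_shapes(list(circle_shape(10, 10, 50)), 64, 64,
                              clip = TRUE))
})

test_that("resolution is the minimum pairwise inter-line distance", {
  segs <- data.frame(x1 = c(0, 0), y1 = c(100, 120), x2 = c(200, 200),
                     y2 = c(100, 120), rho = c(100, 120), theta = c(90, 90),
                     votes = c(5, 5), length = c(200, 200))
  expect_equal(resolution(segs), 20)
  expect_true(is.na(resolution(segs[1, ])))
})

test_that("feature statistics compute replicate mu/sigma with degeneracy", {
  seg <- data.frame(x1 = 0, y1 = 0, x2 = 1, y2 = 1,
                    rho = 0, theta = 20, votes = 3, length = 10)
  segs <- data.frame(x1 = 0, y1 = 0, x2 = 1, y2 = 1, rho = 0,
                     theta = c(10, 20, 30), votes = 3, length = 10)
  # single replicate: plain mean/median of the orientation angles
  fs1 <- feature_statistics(line_fits = list(segs))
  expect_equal(fs1$summary$mu[fs1$summary$statistic == "theta_average"], 110)
  expect_equal(fs1$summary$mu[fs1$summary$statistic == "theta_median"], 110)
  # identical replicates: sigma exactly 0
  fs <- feature_statistics(line_fits = rep(list(seg), 100))
  expect_equal(fs$summary$sigma[fs$summary$statistic == "theta_average"], 0)
  # circle diameters in nm: r = 12.5 px at scale 25 and 158 nm pixels
  circ <- data.frame(a = 0, b = 0, r = 12.5, votes = 5, diameter_nm = NA)
  fc <- feature_statistics(circle_fits = list(circ),
                           camera_pixel_size = 158, scale = 25)
  expect_equal(fc$summary$mu[fc$summary$statistic == "d_average"], 158)
  # zero-detection replicates are excluded with a warning
  expect_warning(
    fz <- feature_statistics(line_fits = list(segs, segs[0, ])),
    "excluded")
  expect_equal(fz$n_excluded, 1)
})

test_that("density sweep runs the full protocol deterministically", {
  mask <- make_line_mask(200, 200, 3, seed = 8)
  sw <- density_sweep(mask, "line", densities = c(0.3, 1),
                      n_replicates = 2, seed_base = 5,
                      params = hough_params("line", min_line_length = 60,
                                            max_gap = 20))
  expect_s3_class(sw, "density_sweep")
  expect_equal(nrow(sw$results), 4)
  expect_equal(nrow(sw$summary), 2)
  expect_true(all(sw$results$cwssim >= 0 & sw$results$cwssim <= 1))
  # full-density replicates are identical data -> identical scores
  full <- sw$results[sw$results$density == 1, ]
  expect_equal(diff(full$cwssim), 0)
  # reproducibility of the whole sweep
  sw2 <- density_sweep(mask, "line", densities = c(0.3, 1),
                       n_replicates = 2, seed_base = 5,
                       params = hough_params("line", min_line_length = 60,
                                             max_gap = 20))
  expect_identical(sw$results, sw2$results)
  # export round trip
  paths <- write_sweep(sw, file.path(tempdir(), "sw.csv"),
                       file.path(tempdir(), "sw.json"))
  expect_true(file.exists(paths["csv"]))
  js <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  expect_equal(nrow(js), 2)
})
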