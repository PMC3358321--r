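test_that("line masks rasterize on the stated geometry", {
  # forced horizontal line: every active pixel shares one y
  m <- make_line_mask(640, 640, endpoints = rbind(c(10, 300, 600, 300)))
  expect_true(all(m$active[, 2] == 300))

  # 45-degree diagonal: normal-form residual of every active pixel <= 0.5 px
  m <- tiny_line_mask()
  s <- m$shapes[[1]]
  expect_equal(s$theta, -45)
  th <- s$theta * pi / 180
  res <- abs(m$active[, 1] * cos(th) + m$active[, 2] * sin(th) - s$rho)
  expect_true(all(res <= 0.5))

  # endpoints satisfy the normal form too
  for (p in list(c(s$x1, s$y1), c(s$x2, s$y2)))
    expect_lt(abs(p[1] * cos(th) + p[2] * sin(th) - s$rho), 0.5)

  # default field emulates a 640 nm x 640 nm region at 1 nm/px
  d <- make_line_mask(seed = 1)
  expect_equal(c(d$width, d$height, d$pixel_scale), c(640, 640, 1))
  expect_error(make_line_mask(1, 640, 3), "dimensions")
})

test_that("circle masks satisfy the circle equation within half a pixel", {
  m <- make_circle_mask(201, 201, circles = rbind(c(100, 100, 50)))
  d <- sqrt((m$active[, 1] - 100)^2 + (m$active[, 2] - 100)^2)
  expect_true(all(abs(d - 50) <= 0.5))

  expect_equal(nrow(make_circle_mask(201, 201, circles =
    matrix(numeric(0), 0, 3))$active), 0)

  # two disjoint circles: active set is the union of the independent rasters
  m2 <- make_circle_mask(300, 300, circles = rbind(c(60, 60, 30),
                                                   c(220, 220, 40)))
  n1 <- nrow(cpp_circle_pixels(60, 60, 30))
  n2 <- nrow(cpp_circle_pixels(220, 220, 40))
  expect_equal(nrow(m2$active), n1 + n2)

  expect_error(make_circle_mask(100, 100, circles = rbind(c(50, 50, 60))),
               "frame")
})

test_that("parallel-line masks share theta with rho spaced by the spacing", {
  m <- make_parallel_line_mask(640, 640, n_lines = 4, spacing = 20, seed = 3)
  th <- vapply(m$shapes, `[[`, 0, "theta")
  rho <- vapply(m$shapes, `[[`, 0, "rho")
  expect_equal(length(unique(round(th, 9))), 1)
  drho <- outer(rho, rho, function(a, b) abs(a - b))
  mult <- drho[upper.tri(drho)] / 20
  expect_equal(mult, round(mult))
  expect_equal(min(drho[upper.tri(drho)]), 20)
  expect_error(make_parallel_line_mask(640, 640, 2, spacing = 0.5),
               "spacing")
})

test_that("stochastic-activation sampling is uniform, exact and reproducible", {
  mask <- make_line_mask(320, 320, 6, seed = 11)
  na <- nrow(mask$active)
  key <- function(m) sort(m[, 1] + 320 * m[, 2])
  # density 1: every active pixel exactly once
  all_pts <- sample_localizations(mask, 1, seed = 5)
  expect_equal(key(as.matrix(all_pts$points)), key(mask$active))
  # forced count and set membership
  locs <- sample_localizations(mask, 0.15, seed = 5)
  expect_equal(nrow(locs$points), round(0.15 * na))
  expect_true(all((locs$points$x + 320 * locs$points$y) %in%
                    (mask$active[, 1] + 320 * mask$active[, 2])))
  # reproducibility
  expect_identical(sample_localizations(mask, 0.3, seed = 9)$points,
                   sample_localizations(mask, 0.3, seed = 9)$points)
  expect_error(sample_localizations(mask, 0), "density")
  expect_error(sample_localizations(mask, 1.2), "density")
})

test_that("per-pixel inclusion frequency matches the sampling density", {
  mask <- make_line_mask(160, 160, 3, seed = 21)
  na <- nrow(mask$active)
  counts <- numeric(na)
  keys <- mask$active[, 1] + 160 * mask$active[, 2]
  for (s in 1:100) {
    l <- sample_localizations(mask, 0.10, seed = 1000 + s)
    counts <- counts + (keys %in% (l$points$x + 160 * l$points$y))
  }
  freq <- counts / 100
  expect_equal(mean(freq), round(0.10 * na) / na, tolerance = 1e-12)
  # 5-sigma binomial band around the target density
  expect_true(all(abs(freq - 0.10) <= 5 * sqrt(0.1 * 0.9 / 100)))
})

test_that("position noise follows the FWHM-parameterized Gaussian", {
  pts <- localization_set(pts_df(rep(100, 10000), rep(100, 10000)))
  expect_identical(apply_position_noise(pts, 0, seed = 1), pts)
  noisy <- apply_position_noise(pts, 5, seed = 2)
  expect_equal(nrow(noisy$points), 10000)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  expect_equal(sd(noisy$points$x - 100), sigma, tolerance = 0.03)
  expect_equal(sd(noisy$points$y - 100), sigma, tolerance = 0.03)
  expect_lt(abs(mean(noisy$points$x - 100)), 0.1)
  expect_lt(abs(mean(noisy$points$y - 100)), 0.1)
  expect_error(apply_position_noise(pts, -1), "fwhm")
})

test_that("displacement radii are Rayleigh with sigma = FWHM/2.3548", {
  n <- 1e5
  pts <- localization_set(pts_df(numeric(n), numeric(n)))
  noisy <- apply_position_noise(pts, 5, seed = 7)
  r <- sqrt(noisy$points$x^2 + noisy$points$y^2)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  ks <- suppressWarnings(
    stats::ks.test(r, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("outlier noise appends the exact off-mask count, off-mask only", {
  mask <- make_line_mask(640, 640, 8, seed = 31)
  locs <- sample_localizations(mask, 0.2, seed = 1)
  expect_identical(add_outlier_noise(locs, mask, 0, seed = 2), locs)
  n_off <- 640 * 640 - nrow(mask$active)
  akey <- mask$active[, 1] + 640 * mask$active[, 2]
  for (dens in c(0.002, 0.005, 0.01, 0.02, 0.05)) {
    out <- add_outlier_noise(locs, mask, dens, seed = 3)
    added <- out$points[-seq_len(nrow(locs$points)), ]
    expect_equal(nrow(added), round(dens * n_off))
    expect_false(any((added$x + 640 * added$y) %in% akey))
    # originals untouched
    expect_identical(out$points[seq_len(nrow(locs$points)), ], locs$points)
  }
  expect_error(add_outlier_noise(locs, mask, 1.5), "density")
})

test_that("mask PNG export round-trips the binary image with a JSON sidecar", {
  mask <- make_circle_mask(120, 120, circles = rbind(c(60, 60, 30)))
  paths <- write_mask_png(mask, file.path(tempdir(), "m.png"))
  img <- png::readPNG(paths["png"])
  expect_equal(sum(img > 0.5), nrow(mask$active))
  shp <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  expect_equal(shp$r, 30)
})
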