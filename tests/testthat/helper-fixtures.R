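# Shared fixtures and independent oracles, built in code at test time.

# points data frame helper
pts_df <- function(x, y) data.frame(x = as.numeric(x), y = as.numeric(y))

# n angularly equispaced pixels of the midpoint-rasterized circle perimeter
circle_perimeter_points <- function(a, b, r, n) circle_points(a, b, r, n)

# Independent line-voting oracle: plain double loop over points and theta
# bins, nearest-rho binning done with explicit arithmetic.
oracle_line_votes <- function(pts, theta_deg, rho_axis) {
  acc <- matrix(0L, length(rho_axis), length(theta_deg))
  step <- rho_axis[2] - rho_axis[1]
  for (i in seq_len(nrow(pts))) {
    for (j in seq_along(theta_deg)) {
      th <- theta_deg[j] * pi / 180
      rho <- pts[i, 1] * cos(th) + pts[i, 2] * sin(th)
      bin <- round((rho - rho_axis[1]) / step) + 1
      if (bin >= 1 && bin <= length(rho_axis))
        acc[bin, j] <- acc[bin, j] + 1L
    }
  }
  acc
}

# Direct (spatial-domain) 2-d "same" convolution oracle, zero padded.
oracle_conv2 <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  hr <- (nrow(k) - 1) %/% 2; hc <- (ncol(k) - 1) %/% 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in seq_len(nrow(k))) for (dj in seq_len(ncol(k))) {
      ii <- i - di + hr + 1; jj <- j - dj + hc + 1
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        s <- s + img[ii, jj] * k[di, dj]
    }
    out[i, j] <- s
  }
  out
}

# Plain (global, non-wavelet) SSIM for the shift-robustness contrast.
plain_ssim <- function(a, b, K1 = 0.01, K2 = 0.03) {
  L <- max(a, b)
  c1 <- (K1 * L)^2; c2 <- (K2 * L)^2
  mx <- mean(a); my <- mean(b)
  vx <- mean((a - mx)^2); vy <- mean((b - my)^2)
  cxy <- mean((a - mx) * (b - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# small deterministic masks reused across tests
tiny_line_mask <- function() {
  make_line_mask(101, 101, endpoints = rbind(c(0, 0, 99, 99)))
}
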