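# FFT-based 2-d "same" convolution with zero padding. `kernel` may be
# complex; dimensions are padded to highly composite sizes via nextn().
conv2_fft <- function(img, kernel) {
  nr <- nrow(img) + nrow(kernel) - 1
  nc <- ncol(img) + ncol(kernel) - 1
  pr <- nextn(nr, c(2, 3, 5)); pc <- nextn(nc, c(2, 3, 5))
  a <- matrix(0, pr, pc); a[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  b <- matrix(0 + 0i, pr, pc)
  b[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  full <- fft(fft(a) * fft(b), inverse = TRUE) / (pr * pc)
  r0 <- (nrow(kernel) - 1) %/% 2; c0 <- (ncol(kernel) - 1) %/% 2
  out <- full[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))]
  if (all(Im(kernel) == 0)) Re(out) else out
}

# Sum of mat over a centred w x w window (zero padded), via summed-area table.
box_sum <- function(mat, w) {
  h <- w %/% 2
  nr <- nrow(mat); nc <- ncol(mat)
  p <- matrix(0, nr + w, nc + w)
  p[h + seq_len(nr), h + seq_len(nc)] <- mat
  s <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed cumulative sums
  s <- t(s)
  z <- matrix(0, nrow(s) + 1, ncol(s) + 1)
  z[-1, -1] <- s
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  z[i1 + w, j1 + w, drop = FALSE] - z[i1, j1 + w, drop = FALSE] -
    z[i1 + w, j1, drop = FALSE] + z[i1, j1, drop = FALSE]
}

# Rotationally symmetric Laplacian-of-Gaussian kernel of standard deviation
# `sigma` and odd size `size`, normalized to zero sum (MATLAB fspecial
# convention).
log_kernel <- function(sigma, size = 2 * ceiling(3 * sigma) + 1) {
  h <- (size - 1) / 2
  g <- outer(-h:h, -h:h, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g <- g / sum(g)
  k <- outer(-h:h, -h:h, function(y, x)
    (x^2 + y^2 - 2 * sigma^2) / sigma^4) * g
  k - mean(k)
}

gaussian_kernel <- function(sigma, size = 2 * ceiling(3 * sigma) + 1) {
  h <- (size - 1) / 2
  g <- outer(-h:h, -h:h, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

# 3x3 unsharp contrast-enhancement kernel, MATLAB fspecial('unsharp', alpha).
unsharp_kernel <- function(alpha = 0.2) {
  matrix(c(-alpha, alpha - 1, -alpha,
           alpha - 1, alpha + 5, alpha - 1,
           -alpha, alpha - 1, -alpha), 3, 3) / (alpha + 1)
}

# Convolve every slice of a 3-d array with the same kernel, computing the
# kernel FFT once.
conv_slices <- function(vol, kernel) {
  d <- dim(vol)
  nr <- d[1] + nrow(kernel) - 1; nc <- d[2] + ncol(kernel) - 1
  pr <- nextn(nr, c(2, 3, 5)); pc <- nextn(nc, c(2, 3, 5))
  kb <- matrix(0, pr, pc)
  kb[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  KB <- fft(kb)
  r0 <- (nrow(kernel) - 1) %/% 2; c0 <- (ncol(kernel) - 1) %/% 2
  out <- array(0, dim = d)
  a <- matrix(0, pr, pc)
  for (k in seq_len(d[3])) {
    a[] <- 0
    a[seq_len(d[1]), seq_len(d[2])] <- vol[, , k]
    full <- Re(fft(fft(a) * KB, inverse = TRUE)) / (pr * pc)
    out[, , k] <- full[r0 + seq_len(d[1]), c0 + seq_len(d[2])]
  }
  out
}
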