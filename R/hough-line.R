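#' Line Hough transform
#'
#' Votes each localization into the \eqn{(\rho, \theta)} parameter space of
#' the normal form \eqn{\rho = x\cos\theta + y\sin\theta}: for every
#' \eqn{\theta} bin the point increments the nearest \eqn{\rho} bin, tracing
#' a sinusoid. Points generated by one line produce sinusoids that intersect
#' at the line's \eqn{(\rho, \theta)}, so the accumulator cell there receives
#' one vote per point.
#'
#' @param points a [localization_set()], or a matrix/data frame with columns
#'   `x`, `y` (0-based pixel coordinates).
#' @param theta_axis \eqn{\theta} bin centres in degrees (default the
#'   preset grid `seq(-90, 89.5, by = 0.5)`).
#' @param rho_axis either the vector of \eqn{\rho} bin centres in pixels, or
#'   a single number taken as the step of a symmetric axis covering the
#'   image diagonal.
#' @param dims image `c(width, height)` used to size a symmetric default
#'   \eqn{\rho} axis; inferred from the points when `NULL`.
#' @return an object of class `line_accumulator`: integer vote matrix
#'   `votes` (\eqn{\rho} by \eqn{\theta}) plus the axes. The vote total is
#'   always `n_points * length(theta_axis)`.
#' @seealso [smooth_line_accumulator()], [detect_lines()], [hough_fit()]
#' @export
line_transform <- function(points, theta_axis = seq(-90, 89.5, by = 0.5),
                           rho_axis = 6, dims = NULL) {
  pts <- as_points(points)
  if (nrow(pts) == 0) stop("empty point set")
  if (length(rho_axis) == 1) {
    if (is.null(dims)) dims <- c(max(pts[, 1]) + 1, max(pts[, 2]) + 1)
    d <- ceiling(sqrt(sum(dims^2)))
    rho_axis <- seq(-d, d, by = rho_axis)
  }
  votes <- cpp_line_vote(pts[, 1], pts[, 2], theta_axis * pi / 180,
                         rho_axis[1], rho_axis[2] - rho_axis[1],
                         length(rho_axis))
  structure(list(votes = votes, theta = theta_axis, rho = rho_axis),
            class = "line_accumulator")
}

#' @export
print.line_accumulator <- function(x, ...) {
  cat(sprintf("line_accumulator: %d rho x %d theta bins, max votes %d\n",
              length(x$rho), length(x$theta), max(x$votes)))
  invisible(x)
}

as_points <- function(points) {
  if (inherits(points, "localization_set")) points <- points$points
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  stopifnot(is.matrix(points), ncol(points) >= 2)
  points[, 1:2, drop = FALSE]
}

#' Median smoothing of the line accumulator
#'
#' Removes spurious isolated vote peaks with a 2-d median filter (zero
#' padded). The default sliding window is the accumulator dimensions divided
#' by 75 (rounded up to odd), the setting used for the real-data grids.
#'
#' @param acc a `line_accumulator` from [line_transform()].
#' @param window length-2 odd window `c(rows, cols)`; default
#'   `dim(votes)/75`.
#' @return a `line_accumulator` with filtered (numeric) votes; the input is
#'   unchanged.
#' @export
smooth_line_accumulator <- function(acc, window = NULL) {
  stopifnot(inherits(acc, "line_accumulator"))
  d <- dim(acc$votes)
  if (is.null(window)) window <- pmax(1, floor(d / 75))
  window <- pmax(1L, as.integer(window))
  window <- window + (window + 1L) %% 2L  # force odd
  if (any(window > d)) stop("median window larger than the accumulator")
  out <- acc
  out$votes <- cpp_median_filter2(acc$votes + 0, window[1], window[2])
  out$smoothed <- TRUE
  out
}

#' Extract line segments from a line accumulator
#'
#' Finds accumulator peaks (local maxima at or above
#' `peak_threshold_frac * max(votes)`, greedily accepted in descending vote
#' order with non-maximum suppression over `peak_separation` bins, ties
#' broken by lower bin index). For each peak the supporting points — those
#' whose normal-form residual \eqn{|\rho - x\cos\theta - y\sin\theta|} is at
#' most `support_residual` (default half a \eqn{\rho} bin) — are ordered
#' along the line and split wherever the gap between consecutive points
#' exceeds `max_gap`; runs at least `min_line_length` long become segments
#' terminated at their extreme supporting points. Points consumed by an
#' emitted segment are removed from the support pool of later (lower-vote)
#' peaks, so the residual ridge of an already-extracted line cannot emit a
#' slightly rotated duplicate.
#'
#' @param acc a (raw or smoothed) `line_accumulator`.
#' @param points the localizations that built the accumulator.
#' @param cfg parameter list from [hough_params()] (`shape = "line"`).
#' @return a data frame of detected segments: `x1, y1, x2, y2, rho,
#'   theta, votes, length`. Empty (zero rows) when no peak reaches the
#'   threshold.
#' @export
detect_lines <- function(acc, points, cfg = hough_params("line")) {
  stopifnot(inherits(acc, "line_accumulator"))
  pts <- as_points(points)
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), rho = numeric(0), theta = numeric(0),
                      votes = numeric(0), length = numeric(0))
  vmax <- max(acc$votes)
  if (vmax <= 0) return(empty)
  thr <- cfg$peak_threshold_frac * vmax
  cand <- cpp_local_maxima3(as.numeric(acc$votes), nrow(acc$votes),
                            ncol(acc$votes), 1L, thr)
  if (nrow(cand) == 0) return(empty)
  ord <- order(-cand[, "value"], cand[, "i"], cand[, "j"])
  cand <- cand[ord, , drop = FALSE]
  sep <- cfg$peak_separation %||% pmax(1, floor(dim(acc$votes) / 50))
  acc_i <- integer(0); acc_j <- integer(0)
  for (t in seq_len(nrow(cand))) {
    i <- cand[t, "i"]; j <- cand[t, "j"]
    if (length(acc_i) == 0 ||
        !any(abs(acc_i - i) <= sep[1] & abs(acc_j - j) <= sep[2])) {
      acc_i <- c(acc_i, i); acc_j <- c(acc_j, j)
    }
    if (length(acc_i) >= cfg$max_peaks) break
  }
  rho_step <- acc$rho[2] - acc$rho[1]
  support <- cfg$support_residual %||% (rho_step / 2)
  segs <- empty
  used <- logical(nrow(pts))
  for (t in seq_along(acc_i)) {
    rho_c <- acc$rho[acc_i[t]]
    theta_c <- acc$theta[acc_j[t]]
    th <- theta_c * pi / 180
    res <- pts[, 1] * cos(th) + pts[, 2] * sin(th) - rho_c
    sel <- which(abs(res) <= support & !used)
    if (length(sel) == 0) next
    # position along the line direction (-sin, cos)
    pos <- -pts[sel, 1] * sin(th) + pts[sel, 2] * cos(th)
    o <- order(pos)
    pos <- pos[o]
    runs <- split(seq_along(pos),
                  cumsum(c(0, diff(pos) > cfg$max_gap)))
    v <- acc$votes[acc_i[t], acc_j[t]]
    for (rn in runs) {
      len <- pos[rn[length(rn)]] - pos[rn[1]]
      if (len < cfg$min_line_length) next
      used[sel[o[rn]]] <- TRUE
      p1 <- c(rho_c * cos(th) - pos[rn[1]] * sin(th),
              rho_c * sin(th) + pos[rn[1]] * cos(th))
      p2 <- c(rho_c * cos(th) - pos[rn[length(rn)]] * sin(th),
              rho_c * sin(th) + pos[rn[length(rn)]] * cos(th))
      segs <- rbind(segs, data.frame(x1 = p1[1], y1 = p1[2], x2 = p2[1],
                                     y2 = p2[2], rho = rho_c,
                                     theta = theta_c, votes = v,
                                     length = len))
    }
  }
  rownames(segs) <- NULL
  segs
}
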