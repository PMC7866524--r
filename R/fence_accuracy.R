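## Positional accuracy against fence lines interpolated from surveyed
## paddock corners: point-to-segment distances and normalised error
## histograms.

#' Build fence lines from a paddock survey
#'
#' One segment per consecutive corner pair, closing the ring, each with a
#' unit normal pointing out of the paddock.
#'
#' @param survey a [paddock_survey()] with at least 3 corners.
#' @return a `data.table` with one row per fence segment: `label`
#'   (`"<from>-<to>"`), endpoints `x0, y0, x1, y1`, `length`, and outward
#'   unit normal `nx, ny`.
#' @export
fit_fence_lines <- function(survey) {
  stopifnot(inherits(survey, "paddock_survey"))
  co <- survey$corners
  n <- nrow(co)
  nxt <- c(2:n, 1L)
  dx <- co$x[nxt] - co$x
  dy <- co$y[nxt] - co$y
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0)) stop("duplicate consecutive corners")
  # signed area > 0 for a counter-clockwise ring; outward normal flips with
  # orientation
  area2 <- sum(co$x * co$y[nxt] - co$x[nxt] * co$y)
  sgn <- if (area2 >= 0) 1 else -1
  data.table(
    label = paste(co$label, co$label[nxt], sep = "-"),
    x0 = co$x, y0 = co$y, x1 = co$x[nxt], y1 = co$y[nxt],
    length = len,
    nx = sgn * dy / len, ny = -sgn * dx / len)
}

## orthogonal distance from points to one segment, clamped to endpoints;
## returns list(distance, signed) where signed uses the outward normal
.seg_dist <- function(px, py, x0, y0, x1, y1, nx, ny) {
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  u <- pmin(pmax(((px - x0) * vx + (py - y0) * vy) / L2, 0), 1)
  cx <- x0 + u * vx; cy <- y0 + u * vy
  dx <- px - cx; dy <- py - cy
  d <- sqrt(dx^2 + dy^2)
  list(distance = d, signed = sign(dx * nx + dy * ny) * d)
}

#' Positional error of a trajectory against fence lines
#'
#' Each (valid) fix is assigned to its nearest fence segment by
#' point-to-segment distance (perpendicular foot clamped to the segment
#' endpoints, so corners are handled without double counting).
#'
#' @param traj a [flock_dataset()] (typically a boundary walk) or a
#'   `data.table` of fixes with columns `t`, `x`, `y`.
#' @param lines fence lines from [fit_fence_lines()].
#' @param signed if `TRUE` report signed distances (positive outside the
#'   ring); default unsigned magnitudes.
#' @return a `data.table` (`t`, `line`, `distance`) with one row per fix.
#' @export
fence_error <- function(traj, lines, signed = FALSE) {
  fx <- if (inherits(traj, "flock_dataset")) valid_fixes(traj)
        else as.data.table(traj)
  if (!nrow(fx)) stop("empty trajectory")
  stopifnot(all(c("t", "x", "y") %in% names(fx)))
  nseg <- nrow(lines)
  dmat <- matrix(NA_real_, nrow(fx), nseg)
  smat <- matrix(NA_real_, nrow(fx), nseg)
  for (s in seq_len(nseg)) {
    r <- .seg_dist(fx$x, fx$y, lines$x0[s], lines$y0[s],
                   lines$x1[s], lines$y1[s], lines$nx[s], lines$ny[s])
    dmat[, s] <- r$distance
    smat[, s] <- r$signed
  }
  best <- max.col(-dmat, ties.method = "first")
  idx <- cbind(seq_len(nrow(fx)), best)
  data.table(t = fx$t, line = lines$label[best],
             distance = if (signed) smat[idx] else dmat[idx])
}

#' Normalised error histogram
#'
#' Bin counts divided by the total count, so the values are fractions that
#' sum to one.
#'
#' @param errors numeric distances (metres), e.g. `fence_error()$distance`.
#' @param bin_width bin width in metres (default 0.01, resolving
#'   RTK-grade errors in the 0--0.25 m range).
#' @return an object of class `error_histogram`: a `data.table` with
#'   `bin_lo`, `bin_hi`, `count` (fraction per bin). A degenerate input
#'   concentrated in a single bin yields a count of 1.0 with a warning.
#' @export
error_histogram <- function(errors, bin_width = 0.01) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  errors <- errors[!is.na(errors)]
  if (!length(errors)) stop("at least one error value required")
  lo <- min(0, floor(min(errors) / bin_width) * bin_width)
  n_bins <- max(1L, as.integer(ceiling((max(errors) - lo) / bin_width)))
  edges <- lo + bin_width * (0:n_bins)
  # right-open bins; the maximum falls in the last bin
  idx <- pmin(findInterval(errors, edges, rightmost.closed = TRUE), n_bins)
  cnt <- tabulate(idx, nbins = n_bins) / length(errors)
  if (any(cnt >= 1))
    warning("all errors fall in a single bin; normalised count is 1.0")
  structure(data.table(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       count = cnt),
            class = c("error_histogram", "data.table", "data.frame"))
}
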