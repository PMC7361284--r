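#' Normalized, averaged fluorescence line profiles
#'
#' Samples each line at `n_samples` equidistant points by bilinear
#' interpolation (pixel centers at `(index - 0.5) * pixel_size_nm`),
#' normalizes each profile, and averages the normalized profiles
#' pointwise. This reproduces the common presentation where several line
#' profiles per condition are normalized and averaged to one mean curve
#' with an SD band.
#'
#' Normalization is min-max by default (`(p - min) / (max - min)`), which
#' maps every profile onto \[0, 1\] before averaging; `"max"` divides by
#' the maximum only. A flat profile (max = min, up to a relative
#' tolerance of 1e-9 absorbing interpolation round-off) cannot be
#' normalized; it is flagged degenerate and excluded from the average (if
#' all profiles are flat, the mean is `NA` and the result is flagged).
#'
#' @param image An [image2d()].
#' @param lines List of lines; each either a numeric vector
#'   `c(x0, y0, x1, y1)` or a list with `start` and `end` (x, y), all in
#'   nanometres from the top-left image corner. Endpoints must lie inside
#'   the image and lines must have positive length.
#' @param n_samples Number of sample points per line (>= 2).
#' @param normalization `"minmax"` (default) or `"max"`.
#' @return Object of class `line_profile`: list with `position_nm`
#'   (sample positions along the line, based on the mean line length),
#'   `mean`, `sd`, `profiles` (n_samples x n_lines matrix of normalized
#'   profiles), `degenerate_lines` (logical per line) and `degenerate`
#'   (overall flag).
#' @export
#' @examples
#' img <- render_image(simulate_scene(scene_params(n_clusters = 4, seed = 5)),
#'                     noise = FALSE)
#' pr <- mean_line_profile(img, list(c(100, 300, 2900, 300)))
mean_line_profile <- function(image, lines, n_samples = 100L,
                              normalization = c("minmax", "max")) {
  stopifnot(inherits(image, "image2d"))
  normalization <- match.arg(normalization)
  if (!is.list(lines) || !length(lines))
    stop_bad_arg("'lines' must be a nonempty list")
  if (!is_count(n_samples) || n_samples < 2)
    stop_bad_arg("'n_samples' must be a count >= 2")
  n_samples <- as.integer(n_samples)
  px <- pixel_size_nm(image)
  m <- as_matrix(image)
  w_nm <- ncol(m) * px
  h_nm <- nrow(m) * px

  ends <- lapply(lines, function(ln) {
    v <- if (is.list(ln)) c(ln$start, ln$end) else ln
    if (!is.numeric(v) || length(v) != 4L || !all(is.finite(v)))
      stop_bad_arg("each line must supply 4 finite coordinates ",
                   "(x0, y0, x1, y1) in nm")
    if (v[1] < 0 || v[1] > w_nm || v[3] < 0 || v[3] > w_nm ||
        v[2] < 0 || v[2] > h_nm || v[4] < 0 || v[4] > h_nm)
      stop_bad_arg("line endpoint outside the image (image is ",
                   w_nm, " x ", h_nm, " nm)")
    if (v[1] == v[3] && v[2] == v[4])
      stop_bad_arg("zero-length line")
    v
  })

  f <- seq(0, 1, length.out = n_samples)
  profiles <- vapply(ends, function(v) {
    x <- v[1] + f * (v[3] - v[1])
    y <- v[2] + f * (v[4] - v[2])
    bilinear_at(m, x / px, y / px)
  }, numeric(n_samples))
  profiles <- matrix(profiles, nrow = n_samples)

  rng <- apply(profiles, 2L, range)
  # flat up to floating-point wobble of the interpolation weights
  degenerate_lines <- (rng[2L, ] - rng[1L, ]) <=
    1e-9 * pmax(abs(rng[1L, ]), abs(rng[2L, ]))
  norm <- profiles
  for (j in which(!degenerate_lines)) {
    if (normalization == "minmax")
      norm[, j] <- (profiles[, j] - rng[1L, j]) / (rng[2L, j] - rng[1L, j])
    else
      norm[, j] <- profiles[, j] / rng[2L, j]
  }
  norm[, degenerate_lines] <- NA_real_

  ok <- !degenerate_lines
  lens <- vapply(ends, function(v) sqrt((v[3] - v[1])^2 + (v[4] - v[2])^2), 0)
  res <- list(
    position_nm = f * mean(lens),
    mean = if (any(ok)) rowMeans(norm[, ok, drop = FALSE]) else
      rep(NA_real_, n_samples),
    sd = if (sum(ok) > 1L) apply(norm[, ok, drop = FALSE], 1L, stats::sd)
      else rep(if (any(ok)) 0 else NA_real_, n_samples),
    profiles = norm,
    n_lines = length(ends),
    degenerate_lines = degenerate_lines,
    degenerate = !any(ok))
  class(res) <- "line_profile"
  res
}

# Bilinear interpolation at continuous pixel coordinates (units of
# pixels; pixel i covers [i-1, i], center i - 0.5). Coordinates are
# clamped to the outermost pixel centers.
bilinear_at <- function(m, xpx, ypx) {
  cx <- pmin(pmax(xpx - 0.5, 0), ncol(m) - 1)
  cy <- pmin(pmax(ypx - 0.5, 0), nrow(m) - 1)
  j0 <- pmin(floor(cx), ncol(m) - 2); j1 <- j0 + 1
  i0 <- pmin(floor(cy), nrow(m) - 2); i1 <- i0 + 1
  tx <- cx - j0
  ty <- cy - i0
  idx <- function(i, j) m[cbind(i + 1L, j + 1L)]
  (1 - ty) * ((1 - tx) * idx(i0, j0) + tx * idx(i0, j1)) +
    ty * ((1 - tx) * idx(i1, j0) + tx * idx(i1, j1))
}

#' @export
print.line_profile <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("<line_profile> %d line(s), all degenerate (flat)\n",
                x$n_lines))
  else
    cat(sprintf("<line_profile> %d line(s) (%d degenerate), %d samples, mean range [%.3f, %.3f]\n",
                x$n_lines, sum(x$degenerate_lines),
                length(x$position_nm), min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
plot.line_profile <- function(x, ...) {
  if (x$degenerate) stop_bad_arg("all profiles degenerate; nothing to plot")
  graphics::plot(x$position_nm, x$mean, type = "l", lwd = 2,
                 xlab = "position along line (nm)",
                 ylab = "normalized intensity",
                 ylim = range(c(x$mean - x$sd, x$mean + x$sd), finite = TRUE),
                 ...)
  graphics::lines(x$position_nm, x$mean + x$sd, lty = 3)
  graphics::lines(x$position_nm, x$mean - x$sd, lty = 3)
  invisible(x)
}
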