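#' Radial grid of annuli
#'
#' Defines the sequence of annuli on which correlation curves are
#' evaluated: inner radii starting at `r_start`, separated by `dr`, each
#' annulus of width `width`. When `dr >= width` the annuli do not
#' overlap; the default `dr = width` tiles `[r_start, r_max)` exactly.
#'
#' @param r_start First inner radius (um), `>= 0`.
#' @param r_max Upper end of the last annulus (um): inner radii run up to
#'   `r_max - width`.
#' @param dr Spacing between consecutive inner radii (um), `> 0`.
#' @param width Annulus width (um), `> 0`. Defaults to `dr`.
#' @return An object of class `"radial_grid"` with fields `r` (inner
#'   radii), `dr` and `width`.
#' @examples
#' g <- radial_grid(r_max = 100, dr = 10)
#' g$r
#' @export
radial_grid <- function(r_start = 0, r_max = 300, dr = 10, width = dr) {
  stopifnot(is.numeric(r_start), is.numeric(r_max),
            is.numeric(dr), is.numeric(width))
  if (width <= 0) stop("annulus width must be positive")
  if (dr <= 0) stop("dr must be positive")
  if (r_start < 0) stop("r_start must be non-negative")
  if (r_start + width > r_max) stop("r_max too small for one annulus")
  r <- seq(r_start, r_max - width, by = dr)
  structure(list(r = r, dr = dr, width = width), class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("radial grid: %d annuli, inner radii %g..%g um, dr=%g, width=%g\n",
              length(x$r), min(x$r), max(x$r), x$dr, x$width))
  invisible(x)
}

# internal constructor for curve outputs
correlation_curve <- function(r, value, statistic, mark_a = NA,
                              mark_b = NA, grid = NULL, extra = NULL) {
  obj <- c(list(r = r, value = value, statistic = statistic,
                mark_a = mark_a, mark_b = mark_b, grid = grid), extra)
  class(obj) <- "correlation_curve"
  obj
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("%s curve (%s vs %s): %d radii\n", x$statistic,
              x$mark_a, x$mark_b, length(x$r)))
  print(utils::head(data.frame(r = x$r, value = x$value), 10))
  if (length(x$r) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ..., xlab = "r (um)",
                                   ylab = x$statistic, type = "l") {
  graphics::plot(x$r, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(r = x$r, value = x$value, statistic = x$statistic,
             mark_a = x$mark_a, mark_b = x$mark_b,
             dr = x$grid$dr, annulus_width = x$grid$width)
}

#' Write a correlation curve to CSV
#'
#' Columns: `r, value, statistic, mark_a, mark_b, dr, annulus_width`.
#'
#' @param curve A `"correlation_curve"`.
#' @param path Output file path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
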