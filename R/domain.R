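#' Rectangular study domain
#'
#' Construct the rectangular region of interest (ROI) on which a point
#' pattern lives. All coordinates are in micrometres. The rectangle is
#' closed: points lying exactly on the boundary are inside.
#'
#' @param x_min,x_max,y_min,y_max Domain limits (um); must satisfy
#'   `x_min < x_max` and `y_min < y_max`.
#' @return An object of class `"domain"`.
#' @examples
#' d <- domain(0, 1000, 0, 1000)
#' domain_area(d)
#' @export
domain <- function(x_min, x_max, y_min, y_max) {
  stopifnot(is.numeric(x_min), is.numeric(x_max),
            is.numeric(y_min), is.numeric(y_max),
            length(x_min) == 1L, length(x_max) == 1L,
            length(y_min) == 1L, length(y_max) == 1L)
  if (!is.finite(x_min) || !is.finite(x_max) ||
      !is.finite(y_min) || !is.finite(y_max)) {
    stop("domain limits must be finite")
  }
  if (x_min >= x_max || y_min >= y_max) {
    stop("domain must satisfy x_min < x_max and y_min < y_max")
  }
  structure(list(x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max),
            class = "domain")
}

#' @rdname domain
#' @param d A `"domain"` object.
#' @export
domain_area <- function(d) {
  stopifnot(inherits(d, "domain"))
  (d$x_max - d$x_min) * (d$y_max - d$y_min)
}

#' Test whether points lie inside a (closed) domain
#'
#' @param x,y Coordinate vectors (um).
#' @param d A `"domain"` object.
#' @return Logical vector.
#' @export
in_domain <- function(x, y, d) {
  stopifnot(inherits(d, "domain"))
  x >= d$x_min & x <= d$x_max & y >= d$y_min & y <= d$y_max
}

#' @export
print.domain <- function(x, ...) {
  cat(sprintf("domain: [%g, %g] x [%g, %g] um (area %g um^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, domain_area(x)))
  invisible(x)
}

#' Marked planar point pattern
#'
#' The central data container: cell centroids on a rectangular domain,
#' each carrying one categorical mark (e.g. cell type) and optionally
#' named continuous marks (e.g. mean stain intensity). This is the marked
#' point process representation of a segmented multiplex image.
#'
#' @param x,y Numeric coordinate vectors (um), equal length.
#' @param marks Categorical mark per point (character or factor). May be
#'   omitted, in which case all points receive the mark `"all"`.
#' @param domain A `"domain"` object. If `NULL`, the tight bounding box of
#'   the points is used.
#' @param continuous Optional data frame (or named list) of continuous
#'   mark columns, one value per point; `NA` marks points for which the
#'   column is undefined.
#' @return An object of class `"point_pattern"` with elements `x`, `y`,
#'   `marks` (character), `continuous` (data frame or `NULL`) and
#'   `domain`.
#' @examples
#' p <- point_pattern(c(10, 20), c(30, 40), c("A", "B"),
#'                    domain(0, 100, 0, 100))
#' n_points(p)
#' mark_counts(p)
#' @export
point_pattern <- function(x, y, marks = NULL, domain = NULL,
                          continuous = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite")
  }
  if (is.null(marks)) marks <- rep("all", n)
  marks <- as.character(marks)
  if (length(marks) != n) stop("marks must have one entry per point")
  if (anyNA(marks) || any(!nzchar(marks))) {
    stop("categorical marks must be non-empty strings")
  }
  if (is.null(domain)) {
    if (n == 0L) stop("cannot infer a domain from an empty pattern")
    domain <- domain(min(x), max(x), min(y), max(y))
  }
  stopifnot(inherits(domain, "domain"))
  if (!all(in_domain(x, y, domain))) {
    stop("all points must lie inside the (closed) domain")
  }
  if (!is.null(continuous)) {
    continuous <- as.data.frame(continuous)
    if (nrow(continuous) != n) {
      stop("continuous mark columns must have one entry per point")
    }
    for (nm in names(continuous)) {
      if (!is.numeric(continuous[[nm]])) {
        stop(sprintf("continuous mark column '%s' must be numeric", nm))
      }
    }
  }
  structure(list(x = x, y = y, marks = marks,
                 continuous = continuous, domain = domain),
            class = "point_pattern")
}

#' @rdname point_pattern
#' @param p A `"point_pattern"`.
#' @export
n_points <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  length(p$x)
}

#' @rdname point_pattern
#' @export
mark_counts <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  table(p$marks)
}

#' Coordinates of the points carrying a given categorical mark
#'
#' @param p A `"point_pattern"`.
#' @param mark A categorical mark label; `NULL` selects all points.
#' @return A two-column matrix of coordinates.
#' @export
mark_coords <- function(p, mark = NULL) {
  stopifnot(inherits(p, "point_pattern"))
  if (is.null(mark)) {
    return(cbind(x = p$x, y = p$y))
  }
  check_mark(p, mark)
  keep <- p$marks == mark
  cbind(x = p$x[keep], y = p$y[keep])
}

# internal: error if a mark label is absent from the pattern
check_mark <- function(p, mark) {
  if (length(mark) != 1L || !mark %in% p$marks) {
    stop(sprintf("mark '%s' not present in the pattern", as.character(mark)))
  }
  invisible(TRUE)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points\n", length(x$x)))
  print(x$domain)
  tab <- table(x$marks)
  cat("marks:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                      collapse = ", "), "\n")
  if (!is.null(x$continuous)) {
    cat("continuous columns:", paste(names(x$continuous), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
plot.point_pattern <- function(x, ..., pch = 16, cex = 0.6) {
  marks <- factor(x$marks)
  graphics::plot(x$x, x$y, col = as.integer(marks), pch = pch, cex = cex,
                 xlim = c(x$domain$x_min, x$domain$x_max),
                 ylim = c(x$domain$y_min, x$domain$y_max),
                 xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  graphics::legend("topright", legend = levels(marks),
                   col = seq_along(levels(marks)), pch = pch, bty = "n")
  invisible(x)
}
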