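#' Area of a disc clipped to the study domain
#'
#' Exact area of the intersection of a closed disc with the rectangular
#' domain, the edge-correction term used by every statistic in the
#' package. Computed in closed form by inclusion-exclusion of signed
#' circular-quadrant areas, not by Monte Carlo, so downstream statistics
#' are deterministic.
#'
#' @param center Disc center: a length-2 vector or a two-column matrix of
#'   centers (um). Centers must lie inside the domain.
#' @param radius Disc radius (um), scalar or one per center; must be
#'   non-negative.
#' @param domain A [domain()] object.
#' @return Area(s) in um^2; `pi * radius^2` when the disc is wholly
#'   interior.
#' @examples
#' d <- domain(0, 1000, 0, 1000)
#' disc_area_in_domain(c(500, 500), 10, d)  # pi * 100, fully interior
#' disc_area_in_domain(c(0, 0), 10, d)      # quarter disc
#' @export
disc_area_in_domain <- function(center, radius, domain) {
  stopifnot(inherits(domain, "domain"))
  cen <- as_centers(center)
  if (any(radius < 0)) stop("radius must be non-negative")
  if (!all(in_domain(cen[, 1L], cen[, 2L], domain))) {
    stop("disc center outside domain")
  }
  disc_rect_area(cen[, 1L], cen[, 2L], radius, domain)
}

#' Area of an annulus clipped to the study domain
#'
#' Edge-corrected annulus area: the area of the annulus with the given
#' inner radius and width, centered at `center`, that falls inside the
#' rectangle. Equals the difference of two clipped disc areas.
#'
#' @inheritParams disc_area_in_domain
#' @param inner_radius Inner radius of the annulus (um), `>= 0`.
#' @param width Annulus width (um), `> 0`.
#' @return Area(s) in um^2.
#' @export
annulus_area_in_domain <- function(center, inner_radius, width, domain) {
  if (any(width <= 0)) stop("annulus width must be positive")
  if (any(inner_radius < 0)) stop("inner radius must be non-negative")
  disc_area_in_domain(center, inner_radius + width, domain) -
    disc_area_in_domain(center, inner_radius, domain)
}

# coerce a center argument (length-2 vector or 2-column matrix) to matrix
as_centers <- function(center) {
  if (is.matrix(center) || is.data.frame(center)) {
    cen <- as.matrix(center)
    if (ncol(cen) != 2L) stop("centers must have two columns")
  } else {
    if (length(center) != 2L) stop("center must be a 2-D point")
    cen <- matrix(as.numeric(center), ncol = 2L)
  }
  storage.mode(cen) <- "double"
  cen
}

# Vectorized closed-form area of disc((cx,cy), r) intersected with the
# rectangle. Uses the signed corner decomposition
#   area = W(X1,Y1) - W(X0,Y1) - W(X1,Y0) + W(X0,Y0)
# in coordinates relative to the center, where W(x,y) is the signed area
# of the disc within the axis-aligned box spanned by the origin and (x,y).
disc_rect_area <- function(cx, cy, r, dom) {
  n <- max(length(cx), length(r))
  cx <- rep_len(cx, n); cy <- rep_len(cy, n); r <- rep_len(r, n)
  x0 <- dom$x_min - cx; x1 <- dom$x_max - cx
  y0 <- dom$y_min - cy; y1 <- dom$y_max - cy
  quad_signed(x1, y1, r) - quad_signed(x0, y1, r) -
    quad_signed(x1, y0, r) + quad_signed(x0, y0, r)
}

quad_signed <- function(x, y, r) {
  sign(x) * sign(y) * quad_area(abs(x), abs(y), r)
}

# area of disc(origin, r) intersected with [0,x] x [0,y], x,y >= 0
quad_area <- function(x, y, r) {
  a <- numeric(length(x))
  pos <- r > 0
  if (!any(pos)) return(a)
  x <- pmin(x, r)                      # box beyond the disc adds nothing
  y <- pmin(y, r)
  corner_in <- pos & (x * x + y * y <= r * r)
  a[corner_in] <- x[corner_in] * y[corner_in]
  rest <- pos & !corner_in
  if (any(rest)) {
    xr <- x[rest]; yr <- y[rest]; rr <- r[rest]
    # the arc crosses the box: flat part up to t* = sqrt(r^2 - y^2),
    # then the circular cap integral of sqrt(r^2 - t^2) from t* to x
    tstar <- sqrt(pmax(rr * rr - yr * yr, 0))
    tstar <- pmin(tstar, xr)
    a[rest] <- tstar * yr + circ_int(xr, rr) - circ_int(tstar, rr)
  }
  a
}

# antiderivative of sqrt(r^2 - t^2): (t sqrt(r^2-t^2) + r^2 asin(t/r)) / 2
circ_int <- function(t, r) {
  t <- pmin(pmax(t, -r), r)
  (t * sqrt(pmax(r * r - t * t, 0)) + r * r * asin(t / r)) / 2
}

#' Minimum enclosing circle of a planar point set
#'
#' Smallest circle containing every input point, computed with Welzl's
#' randomized incremental algorithm (expected linear time). The circle is
#' determined by at most three input points on its boundary. Containment
#' is certified to a relative tolerance of 1e-9 on the radius.
#'
#' @param points A two-column matrix (or data frame) of coordinates (um);
#'   at least one point.
#' @return A list of class `"circle"` with elements `center` (length-2)
#'   and `radius`.
#' @examples
#' min_enclosing_circle(rbind(c(0, 0), c(2, 0)))  # center (1,0), radius 1
#' @export
min_enclosing_circle <- function(points) {
  pts <- as_centers(points)
  n <- nrow(pts)
  if (n < 1L) stop("at least one point is required")
  if (n == 1L) return(circle(pts[1L, ], 0))
  if (n == 2L) return(circle_2(pts[1L, ], pts[2L, ]))
  # deterministic shuffle so the expected-linear-time bound holds without
  # touching the user's RNG stream
  ord <- order(((seq_len(n) * 2654435761) %% 4294967296))
  pts <- pts[ord, , drop = FALSE]
  welzl_mtf(pts)
}

circle <- function(center, radius) {
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "circle")
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf("circle: center (%g, %g), radius %g\n",
              x$center[1L], x$center[2L], x$radius))
  invisible(x)
}

circle_2 <- function(p, q) {
  circle((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
}

# circumcircle of three points; NULL when (numerically) collinear
circle_3 <- function(a, b, c) {
  d <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
              c[1L] * (a[2L] - b[2L]))
  if (abs(d) < 1e-14 * max(1, sum(abs(c(a, b, c))))^2) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2L] - c[2L]) + b2 * (c[2L] - a[2L]) +
           c2 * (a[2L] - b[2L])) / d
  uy <- (a2 * (c[1L] - b[1L]) + b2 * (a[1L] - c[1L]) +
           c2 * (b[1L] - a[1L])) / d
  cen <- c(ux, uy)
  circle(cen, sqrt(sum((a - cen)^2)))
}

in_circle <- function(circ, p, tol = 1e-9) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + tol) + tol * 1e-3
}

# iterative move-to-front Welzl
welzl_mtf <- function(pts) {
  n <- nrow(pts)
  circ <- circle_2(pts[1L, ], pts[2L, ])
  for (i in 3:n) {
    p <- pts[i, ]
    if (in_circle(circ, p)) next
    # p is on the boundary of the new circle
    circ <- circle(p, 0)
    for (j in 1:(i - 1L)) {
      q <- pts[j, ]
      if (in_circle(circ, q)) next
      # p and q on the boundary
      circ <- circle_2(p, q)
      if (j > 1L) for (k in 1:(j - 1L)) {
        s <- pts[k, ]
        if (in_circle(circ, s)) next
        cc <- circle_3(p, q, s)
        circ <- if (is.null(cc)) smallest_diametral(p, q, s) else cc
      }
    }
  }
  circ
}

# for collinear triples the MEC is the diametral circle of the extreme pair
smallest_diametral <- function(p, q, s) {
  cands <- list(circle_2(p, q), circle_2(p, s), circle_2(q, s))
  ok <- vapply(cands, function(cc) {
    in_circle(cc, p) && in_circle(cc, q) && in_circle(cc, s)
  }, logical(1L))
  cands[ok][[which.min(vapply(cands[ok], `[[`, numeric(1L), "radius"))]]
}

# Vectorized MEC radius for triples of points: rows of p1, p2, p3.
# The MEC of three points is the diametral circle of the longest side when
# the triangle is right/obtuse, otherwise the circumcircle.
mec3_radius <- function(p1, p2, p3) {
  d12 <- rowSums((p1 - p2)^2)
  d13 <- rowSums((p1 - p3)^2)
  d23 <- rowSums((p2 - p3)^2)
  dmax <- pmax(d12, d13, d23)
  # right/obtuse <=> the largest squared side >= sum of the other two
  obtuse <- dmax + 1e-12 * dmax >= (d12 + d13 + d23 - dmax)
  r <- numeric(length(d12))
  r[obtuse] <- sqrt(dmax[obtuse]) / 2
  ac <- !obtuse
  if (any(ac)) {
    a <- sqrt(d23[ac]); b <- sqrt(d13[ac]); cc <- sqrt(d12[ac])
    # 4 * area via the cross product of two edges
    cr <- abs((p2[ac, 1L] - p1[ac, 1L]) * (p3[ac, 2L] - p1[ac, 2L]) -
                (p2[ac, 2L] - p1[ac, 2L]) * (p3[ac, 1L] - p1[ac, 1L]))
    r[ac] <- a * b * cc / (2 * cr)
  }
  r
}

# vectorized MEC radius for pairs
mec2_radius <- function(p1, p2) {
  sqrt(rowSums((p1 - p2)^2)) / 2
}
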