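# Independent brute-force oracles used to validate the implementations.
# These are deliberately naive (enumeration / double loops) and share no
# code with the package internals beyond the public geometry helpers
# they are checking against.

# Minimum enclosing circle by exhaustive search: try all pairs as
# diameters and all triples as circumcircles, keep the smallest circle
# that contains every point.
brute_mec <- function(pts) {
  n <- nrow(pts)
  tol <- 1e-9
  contains_all <- function(cen, rad) {
    all(sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2) <=
          rad * (1 + tol) + tol)
  }
  best_r <- Inf
  best <- NULL
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cen <- (pts[i, ] + pts[j, ]) / 2
    rad <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (rad < best_r && contains_all(cen, rad)) {
      best_r <- rad
      best <- list(center = cen, radius = rad)
    }
  }
  if (n >= 3L) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                  cc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(cc^2)
      cen <- c((a2 * (b[2] - cc[2]) + b2 * (cc[2] - a[2]) +
                  c2 * (a[2] - b[2])) / d,
               (a2 * (cc[1] - b[1]) + b2 * (a[1] - cc[1]) +
                  c2 * (b[1] - a[1])) / d)
      rad <- sqrt(sum((a - cen)^2))
      if (rad < best_r && contains_all(cen, rad)) {
        best_r <- rad
        best <- list(center = cen, radius = rad)
      }
    }
  }
  best
}

# Direct double-loop evaluation of the edge-corrected cross-PCF (and, for
# mark_a == mark_b, the PCF) on a point pattern.
brute_cross_pcf <- function(pattern, mark_a, mark_b, grid) {
  same <- identical(mark_a, mark_b)
  ia <- which(pattern$marks == mark_a)
  ib <- which(pattern$marks == mark_b)
  dom <- pattern$domain
  vals <- numeric(length(grid$r))
  for (b in seq_along(grid$r)) {
    lo <- grid$r[b]; hi <- lo + grid$width
    tot <- 0
    for (i in ia) {
      ai <- annulus_area_in_domain(c(pattern$x[i], pattern$y[i]), lo,
                                   grid$width, dom)
      for (j in ib) {
        if (same && i == j) next
        d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                    (pattern$y[i] - pattern$y[j])^2)
        if (d >= lo && d < hi) tot <- tot + 1 / ai
      }
    }
    norm <- if (same) length(ia) * (length(ia) - 1) else {
      length(ia) * length(ib)
    }
    vals[b] <- domain_area(dom) * tot / norm
  }
  vals
}

# Direct evaluation of the categorical-vs-continuous weighted PCF.
brute_wpcf <- function(pattern, mark, column, targets, grid, delta) {
  ia <- which(pattern$marks == mark)
  m <- pattern$continuous[[column]]
  dom <- pattern$domain
  n <- length(pattern$x)
  out <- matrix(NA_real_, length(targets), length(grid$r))
  for (t in seq_along(targets)) {
    w <- pmax(0, 1 - abs(m - targets[t]) / delta)
    w[is.na(w)] <- 0
    W <- sum(w)
    if (W == 0) next
    for (b in seq_along(grid$r)) {
      lo <- grid$r[b]; hi <- lo + grid$width
      tot <- 0
      for (i in ia) {
        ai <- annulus_area_in_domain(c(pattern$x[i], pattern$y[i]), lo,
                                     grid$width, dom)
        for (j in seq_len(n)) {
          if (i == j) next
          d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                      (pattern$y[i] - pattern$y[j])^2)
          if (d >= lo && d < hi) tot <- tot + w[j] / ai
        }
      }
      out[t, b] <- domain_area(dom) * tot / (length(ia) * W)
    }
  }
  out
}

# Monte-Carlo-free pixel-counting estimate of the clipped disc area:
# count 0.1 um pixels whose center lies in both the disc and the domain.
pixel_disc_area <- function(center, radius, dom, h = 0.1) {
  if (radius == 0) return(0)
  # pixels partition the domain itself (anchored at its lower-left corner)
  # so the straight boundary cuts exactly along pixel edges
  xs <- seq(dom$x_min + h / 2, dom$x_max, by = h)
  xs <- xs[abs(xs - center[1]) <= radius]
  ys <- seq(dom$y_min + h / 2, dom$y_max, by = h)
  ys <- ys[abs(ys - center[2]) <= radius]
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- (gx - center[1])^2 + (gy - center[2])^2 <= radius^2
  sum(inside) * h^2
}

# random marked pattern for oracle comparisons
random_pattern <- function(n, dom = domain(0, 100, 0, 100),
                           marks = c("A", "B"), with_continuous = FALSE) {
  x <- runif(n, dom$x_min, dom$x_max)
  y <- runif(n, dom$y_min, dom$y_max)
  lab <- sample(marks, n, replace = TRUE)
  cont <- if (with_continuous) data.frame(m = runif(n)) else NULL
  point_pattern(x, y, lab, dom, continuous = cont)
}

# closed-form CDF of the distance between two uniform points in the unit
# square, valid for 0 <= t <= 1
unit_square_dist_cdf <- function(t) {
  pi * t^2 - 8 * t^3 / 3 + t^4 / 2
}
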