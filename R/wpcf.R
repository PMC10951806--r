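#' Mark-weighting kernel
#'
#' The weight a point with continuous mark `m` receives towards a target
#' mark value `M`. The default triangular kernel is
#'
#'   w(m, M) = max(0, 1 - |m - M| / delta)
#'
#' so weights are 1 at `m = M`, decay linearly, and vanish (compact
#' support) once `|m - M| >= delta`. A Gaussian kernel
#' `exp(-(m - M)^2 / (2 delta^2))` is available as an option.
#'
#' @param m Continuous mark value(s); `NA` yields weight 0.
#' @param target Target mark value(s) `M`.
#' @param delta Kernel half-width (triangular) or standard deviation
#'   (Gaussian) in mark units, `> 0`.
#' @param kernel `"triangular"` (default) or `"gaussian"`.
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' mark_weight(0.5, 0.5, delta = 0.1)    # 1
#' mark_weight(0.55, 0.5, delta = 0.1)   # 0.5
#' @export
mark_weight <- function(m, target, delta, kernel = c("triangular",
                                                     "gaussian")) {
  if (any(delta <= 0)) stop("delta must be positive")
  kernel <- match.arg(kernel)
  w <- switch(kernel,
    triangular = pmax(0, 1 - abs(m - target) / delta),
    gaussian = exp(-(m - target)^2 / (2 * delta^2))
  )
  w[is.na(w)] <- 0
  w
}

#' Weighted pair correlation function (categorical vs continuous mark)
#'
#' Generalizes the cross-PCF to a continuous partner mark without
#' thresholding it into classes. For each target mark value `M` and
#' radius bin,
#'
#'   wPCF(M, r) = |D| / (N_C W_M) * sum_{i in C} sum_{j != i}
#'                w(m_j, M) 1(d_ij in bin) / A_i(r)
#'
#' where the inner sum runs over all points carrying the continuous mark,
#' each weighted by how closely its mark matches `M`, and
#' `W_M = sum_j w(m_j, M)` is the total weight at that target. Each row
#' (fixed `M`) reads like a cross-PCF between the categorical mark and
#' "cells with mark near M": 1 at the CSR level, above 1 clustering,
#' below 1 exclusion. Points whose continuous mark is `NA` contribute no
#' weight. Rows with `W_M = 0` are `NA` (missing), never 0.
#'
#' @param pattern A [point_pattern()] with the continuous column present.
#' @param categorical_mark Mark of the annulus-center points.
#' @param continuous_column Name of the continuous mark column.
#' @param targets Target mark values `M`; default 101 evenly spaced
#'   values spanning the observed mark range.
#' @param grid A [radial_grid()].
#' @param delta Kernel half-width; default one tenth of the observed mark
#'   range.
#' @param kernel Passed to [mark_weight()].
#' @return A list of class `"wpcf_surface"` with `targets`, `r`, `values`
#'   (targets x radii matrix), `W` (total weight per target), and the
#'   parameters used.
#' @export
wpcf <- function(pattern, categorical_mark, continuous_column,
                 targets = NULL, grid = radial_grid(), delta = NULL,
                 kernel = "triangular") {
  stopifnot(inherits(pattern, "point_pattern"), inherits(grid, "radial_grid"))
  check_mark(pattern, categorical_mark)
  m <- continuous_marks(pattern, continuous_column)
  rng <- range(m, na.rm = TRUE)
  if (is.null(delta)) delta <- default_delta(rng)
  if (is.null(targets)) targets <- seq(rng[1L], rng[2L], length.out = 101L)
  ca <- mark_coords(pattern, categorical_mark)
  all_pts <- cbind(pattern$x, pattern$y)
  dmat <- cross_dist(ca, all_pts)
  # exclude self-pairs: the i-th center is some row of the full pattern
  self <- which(pattern$marks == categorical_mark)
  dmat[cbind(seq_along(self), self)] <- Inf
  # V[b, j] = sum_i 1(d_ij in bin b) / A_i(b)
  nbins <- length(grid$r)
  V <- matrix(0, nbins, ncol(dmat))
  for (b in seq_len(nbins)) {
    lo <- grid$r[b]; hi <- lo + grid$width
    A <- annulus_area_in_domain(ca, lo, grid$width, pattern$domain)
    A[A == 0] <- Inf                 # empty annulus contributes nothing
    V[b, ] <- colSums((dmat >= lo & dmat < hi) / A)
  }
  Wmat <- weight_matrix(m, targets, delta, kernel)  # n_points x n_targets
  W <- colSums(Wmat)
  vals <- t(V %*% Wmat)                        # targets x radii
  vals <- vals * domain_area(pattern$domain) / (nrow(ca) * W)
  vals[W == 0, ] <- NA_real_
  structure(list(targets = targets, r = grid$r, values = vals, W = W,
                 categorical_mark = categorical_mark,
                 continuous_column = continuous_column, delta = delta,
                 kernel = kernel, grid = grid),
            class = "wpcf_surface")
}

#' Weighted PCF for two continuous marks
#'
#' Compares point clouds through two continuous marks simultaneously: for
#' target values `M1`, `M2` and a radius bin,
#'
#'   wPCF(M1, M2, r) = |D| / (W_M1 W_M2) * sum_i sum_{j != i}
#'                     w1(m1_i, M1) w2(m2_j, M2) 1(d_ij in bin) / A_i(r)
#'
#' The two kernels may use different half-widths. Entries where either
#' total weight is zero are `NA`.
#'
#' @inheritParams wpcf
#' @param column_1,column_2 Names of the two continuous mark columns;
#'   column 1 weights the annulus centers, column 2 the counted points.
#' @param targets_1,targets_2 Target grids for each mark (defaults: 26
#'   evenly spaced values over each observed range).
#' @param delta_1,delta_2 Kernel half-widths (defaults: one tenth of each
#'   observed range).
#' @return A list of class `"wpcf2_surface"` with `targets_1`,
#'   `targets_2`, `r`, `values` (3-D array targets_1 x targets_2 x
#'   radii), `W1`, `W2`, and the parameters used.
#' @export
wpcf_continuous <- function(pattern, column_1, column_2,
                            targets_1 = NULL, targets_2 = NULL,
                            grid = radial_grid(), delta_1 = NULL,
                            delta_2 = NULL, kernel = "triangular") {
  stopifnot(inherits(pattern, "point_pattern"), inherits(grid, "radial_grid"))
  m1 <- continuous_marks(pattern, column_1)
  m2 <- continuous_marks(pattern, column_2)
  rng1 <- range(m1, na.rm = TRUE); rng2 <- range(m2, na.rm = TRUE)
  if (is.null(delta_1)) delta_1 <- default_delta(rng1)
  if (is.null(delta_2)) delta_2 <- default_delta(rng2)
  if (is.null(targets_1)) targets_1 <- seq(rng1[1L], rng1[2L],
                                           length.out = 26L)
  if (is.null(targets_2)) targets_2 <- seq(rng2[1L], rng2[2L],
                                           length.out = 26L)
  pts <- cbind(pattern$x, pattern$y)
  n <- nrow(pts)
  dmat <- cross_dist(pts, pts)
  diag(dmat) <- Inf
  W1mat <- weight_matrix(m1, targets_1, delta_1, kernel)
  W2mat <- weight_matrix(m2, targets_2, delta_2, kernel)
  W1 <- colSums(W1mat); W2 <- colSums(W2mat)
  nbins <- length(grid$r)
  vals <- array(NA_real_, c(length(targets_1), length(targets_2), nbins))
  area <- domain_area(pattern$domain)
  for (b in seq_len(nbins)) {
    lo <- grid$r[b]; hi <- lo + grid$width
    A <- annulus_area_in_domain(pts, lo, grid$width, pattern$domain)
    A[A == 0] <- Inf                 # empty annulus contributes nothing
    Tb <- (dmat >= lo & dmat < hi) / A
    vals[, , b] <- crossprod(W1mat, Tb %*% W2mat) * area / outer(W1, W2)
  }
  vals[W1 == 0, , ] <- NA_real_
  vals[, W2 == 0, ] <- NA_real_
  if (n < 2L) vals[] <- NA_real_         # no pairs: surface is missing
  structure(list(targets_1 = targets_1, targets_2 = targets_2,
                 r = grid$r, values = vals, W1 = W1, W2 = W2,
                 column_1 = column_1, column_2 = column_2,
                 delta_1 = delta_1, delta_2 = delta_2, kernel = kernel,
                 grid = grid),
            class = "wpcf2_surface")
}

weight_matrix <- function(m, targets, delta, kernel) {
  matrix(vapply(targets, function(M) mark_weight(m, M, delta, kernel),
                numeric(length(m))),
         nrow = length(m), ncol = length(targets))
}

default_delta <- function(rng) {
  d <- diff(rng) / 10
  if (d <= 0) 1 else d
}

continuous_marks <- function(pattern, column) {
  if (is.null(pattern$continuous) || !column %in% names(pattern$continuous)) {
    stop(sprintf("continuous mark column '%s' not present", column))
  }
  pattern$continuous[[column]]
}

#' @export
print.wpcf_surface <- function(x, ...) {
  cat(sprintf(
    "wPCF surface: %s vs '%s', %d targets x %d radii, delta=%g (%s kernel)\n",
    x$categorical_mark, x$continuous_column, length(x$targets),
    length(x$r), x$delta, x$kernel))
  invisible(x)
}

#' @export
plot.wpcf_surface <- function(x, ..., n_levels = 64) {
  ok <- is.finite(x$values)
  zmax <- max(abs(x$values[ok] - 1))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(n_levels)
  graphics::image(x$targets, x$r, x$values, col = pal,
                  zlim = c(1 - zmax, 1 + zmax),
                  xlab = sprintf("target mark (%s)", x$continuous_column),
                  ylab = "r (um)", ...)
  invisible(x)
}

#' @export
as.data.frame.wpcf_surface <- function(x, ...) {
  out <- expand.grid(target_mark = x$targets, r = x$r)
  out$value <- as.vector(x$values)
  out$W_M <- rep(x$W, times = length(x$r))
  out
}

#' @export
as.data.frame.wpcf2_surface <- function(x, ...) {
  out <- expand.grid(target_1 = x$targets_1, target_2 = x$targets_2,
                     r = x$r)
  out$value <- as.vector(x$values)
  out
}

#' Write a wPCF surface to CSV (long form)
#'
#' For [wpcf()]: columns `target_mark, r, value, W_M`. For
#' [wpcf_continuous()]: columns `target_1, target_2, r, value`.
#'
#' @param surface A `"wpcf_surface"` or `"wpcf2_surface"`.
#' @param path Output file path.
#' @export
write_wpcf <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}
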