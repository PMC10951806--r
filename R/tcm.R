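#' Per-cell local cross-correlation Gamma
#'
#' For every point carrying `mark_a`, Gamma is the ratio of the local
#' density of `mark_b` points within distance `r_tcm` (disc-area edge
#' corrected) to the global density of `mark_b`:
#'
#'   Gamma_i = (n_b(i, r) / A_r(x_i)) / (N_B / |D|)
#'
#' This is the contribution of point i to the cross-PCF for a single
#' annulus with inner radius 0 and width `r_tcm` (a local, K-function-type
#' quantity). Gamma = 1 is the CSR level; > 1 local attraction of B
#' around that A cell, < 1 local depletion. A point carrying both marks
#' does not count itself.
#'
#' @param pattern A [point_pattern()].
#' @param mark_a Mark of the focal points (one Gamma per such point).
#' @param mark_b Mark of the counted points; at least one required.
#' @param r_tcm Correlation radius (um), `> 0`. Default 50 um, roughly
#'   two to three cell diameters.
#' @param alpha Saturation cap used for the linearized values, `> 1`.
#' @return A list of class `"local_gamma"` with `gamma`, `gamma_prime`
#'   (both one value per `mark_a` point), `coords`, `r_tcm`, `alpha`.
#' @seealso [tcm_surface()], [linearize_gamma()]
#' @export
local_gamma <- function(pattern, mark_a, mark_b, r_tcm = 50, alpha = 5) {
  stopifnot(inherits(pattern, "point_pattern"))
  check_mark(pattern, mark_a)
  check_mark(pattern, mark_b)
  if (r_tcm <= 0) stop("r_tcm must be positive")
  nb_tot <- sum(pattern$marks == mark_b)
  if (nb_tot < 1L) stop(sprintf("no points with mark '%s'", mark_b))
  ca <- mark_coords(pattern, mark_a)
  cb <- mark_coords(pattern, mark_b)
  dmat <- cross_dist(ca, cb)
  if (identical(mark_a, mark_b)) diag(dmat) <- Inf   # self-exclusion
  counts <- rowSums(dmat < r_tcm)
  areas <- disc_area_in_domain(ca, r_tcm, pattern$domain)
  gamma <- (counts / areas) / (nb_tot / domain_area(pattern$domain))
  structure(list(gamma = gamma,
                 gamma_prime = linearize_gamma(gamma, alpha),
                 coords = ca, r_tcm = r_tcm, alpha = alpha,
                 mark_a = mark_a, mark_b = mark_b),
            class = "local_gamma")
}

#' Fold-change-symmetric linearization of Gamma
#'
#' Gamma is a ratio to the CSR expectation, so its raw scale is
#' asymmetric: three times as many points as expected gives Gamma = 3,
#' three times fewer gives Gamma = 1/3. The linearized mark Gamma' puts
#' clustering and exclusion on a common linear scale:
#'
#'   Gamma' = min(Gamma, alpha) - 1          for Gamma >= 1
#'   Gamma' = 1 - min(1 / Gamma, alpha)      for 0 < Gamma < 1
#'   Gamma' = -(alpha - 1)                   for Gamma = 0
#'
#' so Gamma = 1 maps to 0, a k-fold enrichment and a k-fold depletion map
#' to +/-(k - 1), and values saturate at +/-(alpha - 1); `alpha` is the
#' maximal fold change the map resolves.
#'
#' @param gamma Non-negative Gamma value(s).
#' @param alpha Saturation cap, `> 1` (default 5).
#' @return Gamma' value(s) in `[-(alpha - 1), alpha - 1]`.
#' @examples
#' linearize_gamma(c(1, 3, 1/3, 100), alpha = 5)  # 0, 2, -2, 4
#' @export
linearize_gamma <- function(gamma, alpha = 5) {
  if (any(alpha <= 1)) stop("alpha must exceed 1")
  if (any(gamma < 0)) stop("gamma must be non-negative")
  out <- numeric(length(gamma))
  up <- gamma >= 1
  out[up] <- pmin(gamma[up], alpha) - 1
  dn <- gamma < 1 & gamma > 0
  out[dn] <- 1 - pmin(1 / gamma[dn], alpha)
  out[gamma == 0] <- -(alpha - 1)
  out
}

#' Topographical correlation map
#'
#' A raster over the domain that localizes where two cell types are
#' spatially correlated. Each `mark_a` cell contributes a Gaussian kernel
#' centered at its location, scaled by its linearized local correlation
#' Gamma' with `mark_b`:
#'
#'   TCM(x) = sum_{i in A} Gamma'_i exp(-|x - x_i|^2 / (2 sigma^2))
#'
#' Positive regions indicate A-B colocalization above the CSR level at
#' scales up to `r_tcm`; negative regions indicate exclusion. The map is
#' asymmetric in its marks by construction (kernels sit on A cells).
#' Kernels are unnormalized, so a single isolated cell contributes a peak
#' of height Gamma'.
#'
#' @inheritParams local_gamma
#' @param sigma Kernel standard deviation (um); default `r_tcm / 2`, so
#'   the kernel's ~2 sigma support matches the correlation radius.
#' @param grid_spacing Raster node spacing (um); nodes lie on a regular
#'   grid anchored at the domain's lower-left corner, boundary inclusive.
#' @return A list of class `"tcm_surface"` with `x`, `y` (node
#'   coordinates), `z` (matrix, `length(x)` rows by `length(y)` columns),
#'   and the parameters used.
#' @export
tcm_surface <- function(pattern, mark_a, mark_b, r_tcm = 50, sigma = r_tcm / 2,
                        grid_spacing = 10, alpha = 5) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (sigma <= 0) stop("sigma must be positive")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  dom <- pattern$domain
  xs <- seq(dom$x_min, dom$x_max, by = grid_spacing)
  ys <- seq(dom$y_min, dom$y_max, by = grid_spacing)
  z <- matrix(0, length(xs), length(ys))
  if (any(pattern$marks == mark_a)) {
    lg <- local_gamma(pattern, mark_a, mark_b, r_tcm, alpha)
    # separable kernel: z = Kx^T diag(gamma') Ky summed over points
    kx <- exp(-outer(lg$coords[, 1L], xs, function(a, b) (a - b)^2) /
                (2 * sigma^2))
    ky <- exp(-outer(lg$coords[, 2L], ys, function(a, b) (a - b)^2) /
                (2 * sigma^2))
    z <- crossprod(kx * lg$gamma_prime, ky)
  }
  structure(list(x = xs, y = ys, z = z, r_tcm = r_tcm, sigma = sigma,
                 grid_spacing = grid_spacing, alpha = alpha,
                 mark_a = mark_a, mark_b = mark_b),
            class = "tcm_surface")
}

#' @export
print.tcm_surface <- function(x, ...) {
  cat(sprintf(
    "TCM surface (%s vs %s): %d x %d nodes, spacing %g um, range [%.3g, %.3g]\n",
    x$mark_a, x$mark_b, length(x$x), length(x$y), x$grid_spacing,
    min(x$z), max(x$z)))
  invisible(x)
}

#' @export
plot.tcm_surface <- function(x, ..., n_levels = 64) {
  zmax <- max(abs(x$z))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(n_levels)
  graphics::image(x$x, x$y, x$z, col = pal,
                  zlim = c(-zmax, zmax), xlab = "x (um)", ylab = "y (um)",
                  asp = 1, ...)
  invisible(x)
}

#' Write a TCM surface to disk
#'
#' Writes (i) a long-form CSV with columns `x, y, value`, (ii) a
#' whitespace-delimited plain-text raster matrix (rows = y from low to
#' high), and (iii) a JSON sidecar recording the parameters.
#'
#' @param surface A `"tcm_surface"`.
#' @param path Base output path; `.csv`, `.txt` and `.json` suffixes are
#'   appended.
#' @return Invisibly, the three file paths written.
#' @export
write_tcm <- function(surface, path) {
  stopifnot(inherits(surface, "tcm_surface"))
  long <- expand.grid(x = surface$x, y = surface$y)
  long$value <- as.vector(surface$z)
  csv <- paste0(path, ".csv")
  txt <- paste0(path, ".txt")
  json <- paste0(path, ".json")
  utils::write.csv(long, csv, row.names = FALSE)
  utils::write.table(t(surface$z), txt, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(r_tcm = surface$r_tcm, alpha = surface$alpha,
         sigma = surface$sigma, grid_spacing = surface$grid_spacing,
         mark_a = surface$mark_a, mark_b = surface$mark_b,
         n_x = length(surface$x), n_y = length(surface$y)),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, raster = txt, sidecar = json))
}
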