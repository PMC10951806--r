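#' Empirical pair correlation function with annulus-area edge correction
#'
#' For each annulus `[r, r + width)` of the radial grid, the PCF is
#'
#'   g(r) = |D| / (N_C (N_C - 1)) * sum_{i != j} 1(d_ij in [r, r+w)) / A_i(r)
#'
#' where the sum runs over ordered pairs of points carrying mark `C`,
#' `|D|` is the domain area and `A_i(r)` is the area of the annulus
#' centered at point `i` that lies inside the domain (edge correction).
#' Under complete spatial randomness (CSR) the PCF is 1; values above 1
#' indicate clustering at that length scale, values below 1 exclusion.
#'
#' @param pattern A [point_pattern()].
#' @param mark Categorical mark label; at least two points must carry it.
#' @param grid A [radial_grid()].
#' @return A `"correlation_curve"` with fields `r` (inner radii) and
#'   `value`.
#' @seealso [cross_pcf()], [csr_envelope()]
#' @examples
#' p <- generate_csr(domain(0, 1000, 0, 1000), c(A = 200), seed = 1)
#' g <- pcf(p, "A", radial_grid(r_max = 150))
#' @export
pcf <- function(pattern, mark, grid = radial_grid()) {
  stopifnot(inherits(pattern, "point_pattern"))
  check_mark(pattern, mark)
  if (sum(pattern$marks == mark) < 2L) {
    stop(sprintf("need at least 2 points with mark '%s'", mark))
  }
  cross_pcf(pattern, mark, mark, grid)
}

#' Empirical cross-type pair correlation function
#'
#' Generalizes [pcf()] to pairs of distinct marks:
#'
#'   g_AB(r) = |D| / (N_A N_B) * sum_{i in A} sum_{j in B}
#'             1(d_ij in [r, r+w)) / A_i(r)
#'
#' Annuli are centered on the mark-`a` points, so the statistic is
#' asymmetric only through the edge-correction areas. When
#' `mark_a == mark_b` self-pairs are excluded and the normalization
#' becomes `N_C (N_C - 1)`, which makes the result identical to [pcf()].
#'
#' @inheritParams pcf
#' @param mark_a Mark of the annulus centers.
#' @param mark_b Mark of the counted points.
#' @return A `"correlation_curve"`.
#' @export
cross_pcf <- function(pattern, mark_a, mark_b, grid = radial_grid()) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(grid, "radial_grid"))
  check_mark(pattern, mark_a)
  check_mark(pattern, mark_b)
  same <- identical(mark_a, mark_b)
  ca <- mark_coords(pattern, mark_a)
  cb <- mark_coords(pattern, mark_b)
  na <- nrow(ca); nb <- nrow(cb)
  if (same && na < 2L) {
    stop(sprintf("need at least 2 points with mark '%s'", mark_a))
  }
  dmat <- cross_dist(ca, cb)
  if (same) diag(dmat) <- Inf             # exclude self-pairs
  norm <- if (same) na * (na - 1) else na * nb
  value <- pcf_engine(dmat, ca, grid, pattern$domain) *
    domain_area(pattern$domain) / norm
  correlation_curve(grid$r, value,
                    statistic = if (same) "pcf" else "cross_pcf",
                    mark_a = mark_a, mark_b = mark_b, grid = grid)
}

# sum over i of (pair count in bin) / (annulus area at point i), per bin
pcf_engine <- function(dmat, centers, grid, dom) {
  nb <- length(grid$r)
  areas <- matrix(0, nrow(centers), nb)
  for (b in seq_len(nb)) {
    areas[, b] <- annulus_area_in_domain(centers, grid$r[b], grid$width, dom)
  }
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- grid$r[b]; hi <- lo + grid$width
    counts <- rowSums(dmat >= lo & dmat < hi)
    # an annulus wholly outside the domain can hold no points: 0, not 0/0
    ok <- areas[, b] > 0
    out[b] <- sum(counts[ok] / areas[ok, b])
  }
  out
}

# full cross-distance matrix (na x nb); patterns here are at most a few
# thousand points, so the dense matrix is the fastest route in R
cross_dist <- function(ca, cb) {
  a2 <- rowSums(ca^2)
  b2 <- rowSums(cb^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(ca, cb)
  sqrt(pmax(d2, 0))
}
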