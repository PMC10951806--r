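#' Minimum-enclosing-circle radii of all k-type tuples
#'
#' Enumerates every tuple taking one point per requested mark and returns
#' the radius of each tuple's minimum enclosing circle (MEC), truncated
#' to radii `<= r_max`. Tuples whose maximum pairwise distance exceeds
#' `2 * r_max` are pruned before any circle is computed; this is exact
#' because the MEC radius is at least half the largest pairwise distance.
#'
#' The number of tuples is the product of the per-mark counts, so cost
#' grows multiplicatively in the marks; `r_max` keeps the output (and,
#' via pruning, much of the work) bounded.
#'
#' @param pattern A [point_pattern()].
#' @param marks Character vector of `k >= 2` mark labels, all present in
#'   the pattern. Repeated labels are allowed and reuse the same points.
#' @param r_max Largest radius retained (um), `> 0`.
#' @return Numeric vector of MEC radii (um), one per retained tuple.
#' @export
triplet_mec_radii <- function(pattern, marks, r_max = 300) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (length(marks) < 2L) stop("at least two marks are required")
  if (r_max <= 0) stop("r_max must be positive")
  for (m in marks) check_mark(pattern, m)
  coords <- lapply(marks, function(m) mark_coords(pattern, m))
  tuple_mec_radii(coords, r_max)
}

# coords: list of k coordinate matrices; returns MEC radii <= r_max of the
# cartesian product of rows, with exact pairwise-distance pruning
tuple_mec_radii <- function(coords, r_max) {
  k <- length(coords)
  ns <- vapply(coords, nrow, integer(1L))
  idx <- as.matrix(expand.grid(lapply(ns, seq_len)))
  pts <- lapply(seq_len(k), function(j) coords[[j]][idx[, j], , drop = FALSE])
  # prune on pairwise distances: d_max > 2 r_max  =>  MEC radius > r_max
  keep <- rep(TRUE, nrow(idx))
  lim2 <- (2 * r_max)^2
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    keep <- keep & rowSums((pts[[a]] - pts[[b]])^2) <= lim2
  }
  if (!any(keep)) return(numeric(0))
  pts <- lapply(pts, function(m) m[keep, , drop = FALSE])
  r <- switch(as.character(k),
    "2" = mec2_radius(pts[[1L]], pts[[2L]]),
    "3" = mec3_radius(pts[[1L]], pts[[2L]], pts[[3L]]),
    vapply(seq_len(nrow(pts[[1L]])), function(i) {
      min_enclosing_circle(do.call(rbind, lapply(pts, function(m) m[i, ])))$radius
    }, numeric(1L))
  )
  r[r <= r_max]
}

#' CSR distribution of k-tuple minimum-enclosing-circle radii
#'
#' Monte-Carlo estimate of the probability that the MEC radius of `k`
#' points drawn independently and uniformly in the domain falls in each
#' radius bin of the grid. This is the reference distribution against
#' which observed tuple neighbourhoods are compared in [ncf()]; sampling
#' on the same domain as the data means edge effects are absorbed by the
#' null, so no analytic edge correction is needed.
#'
#' @param domain A [domain()].
#' @param k Tuple size, `>= 2`.
#' @param grid A [radial_grid()] of radius bins.
#' @param n_samples Number of random tuples, `>= 1`. The default 1e5
#'   gives per-bin standard errors reported in the output.
#' @param seed Integer seed; the estimate is deterministic given the seed.
#' @return A list with `r` (inner radii), `prob` (per-bin probability of
#'   the MEC radius falling in `[r, r + width)`), `cum_prob` (probability
#'   of radius `< r + width`), `stderr` (binomial Monte-Carlo standard
#'   error per bin), `n_samples`, `k`.
#' @export
csr_mec_probability <- function(domain, k = 3, grid = radial_grid(),
                                n_samples = 1e5, seed = NULL) {
  stopifnot(inherits(domain, "domain"), inherits(grid, "radial_grid"))
  if (k < 2) stop("k must be at least 2")
  if (n_samples < 1) stop("n_samples must be at least 1")
  radii <- with_seed(seed, {
    pts <- lapply(seq_len(k), function(j) {
      cbind(stats::runif(n_samples, domain$x_min, domain$x_max),
            stats::runif(n_samples, domain$y_min, domain$y_max))
    })
    if (k == 2L) {
      mec2_radius(pts[[1L]], pts[[2L]])
    } else if (k == 3L) {
      mec3_radius(pts[[1L]], pts[[2L]], pts[[3L]])
    } else {
      vapply(seq_len(n_samples), function(i) {
        min_enclosing_circle(do.call(rbind, lapply(pts, function(m) m[i, ])))$radius
      }, numeric(1L))
    }
  })
  prob <- bin_props(radii, grid)
  cum_prob <- vapply(grid$r + grid$width,
                     function(u) mean(radii < u), numeric(1L))
  list(r = grid$r, prob = prob,
       cum_prob = cum_prob,
       stderr = sqrt(prob * (1 - prob) / n_samples),
       n_samples = n_samples, k = k)
}

# per-bin proportions for possibly overlapping [r, r+width) bins
bin_props <- function(values, grid) {
  vapply(grid$r, function(lo) {
    mean(values >= lo & values < lo + grid$width)
  }, numeric(1L))
}

#' Neighbourhood correlation function for k cell types
#'
#' Compares how often one point of each of `k` marks is found together in
#' a small neighbourhood against the CSR expectation. A tuple's
#' neighbourhood size is the radius of its minimum enclosing circle; for
#' each radius bin the NCF is
#'
#'   NCF(r) = observed tuple count in bin / ((prod_i N_i) * p_CSR(bin))
#'
#' where `p_CSR` is estimated by [csr_mec_probability()] on the same
#' domain. NCF > 1 means the marks co-occur in neighbourhoods of that
#' radius more often than chance; NCF < 1 less often; 0 means no such
#' neighbourhood exists in the data. Bins whose expected count is zero
#' are reported as `NA` (missing), never as 0.
#'
#' @inheritParams triplet_mec_radii
#' @param grid A [radial_grid()] of radius bins; its upper end also sets
#'   `r_max` for tuple enumeration.
#' @param n_samples Monte-Carlo samples for the CSR null.
#' @param seed Integer seed for the CSR null (observed counts are always
#'   deterministic).
#' @param cumulative If `TRUE`, counts are of tuples with MEC radius
#'   `< r + width` (non-decreasing in r) rather than per bin.
#' @return A list of class `"ncf_curve"` with `r`, `value`,
#'   `observed_counts`, `expected_counts`, `mc_stderr` (Monte-Carlo
#'   standard error of `value`), `k`, `n_csr_samples`, `cumulative`.
#' @examples
#' p <- generate_dataset_2(seed = 1, variant = "triplet")
#' curve <- ncf(p, c("A", "B", "C"), radial_grid(r_max = 100),
#'              n_samples = 2e4, seed = 2)
#' @export
ncf <- function(pattern, marks, grid = radial_grid(), n_samples = 1e5,
                seed = NULL, cumulative = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(grid, "radial_grid"))
  r_max <- max(grid$r) + grid$width
  radii <- triplet_mec_radii(pattern, marks, r_max = r_max)
  n_tuples <- prod(vapply(marks, function(m) sum(pattern$marks == m),
                          numeric(1L)))
  null <- csr_mec_probability(pattern$domain, k = length(marks),
                              grid = grid, n_samples = n_samples,
                              seed = seed)
  if (cumulative) {
    observed <- vapply(grid$r + grid$width,
                       function(u) sum(radii < u), numeric(1L))
    p <- null$cum_prob
  } else {
    observed <- vapply(grid$r, function(lo) {
      sum(radii >= lo & radii < lo + grid$width)
    }, numeric(1L))
    p <- null$prob
  }
  se_p <- sqrt(p * (1 - p) / n_samples)
  expected <- n_tuples * p
  value <- ifelse(expected > 0, observed / expected, NA_real_)
  mc_stderr <- ifelse(p > 0, value * se_p / p, NA_real_)
  structure(list(r = grid$r, value = value,
                 observed_counts = observed, expected_counts = expected,
                 mc_stderr = mc_stderr, k = length(marks), marks = marks,
                 n_csr_samples = n_samples, cumulative = cumulative,
                 grid = grid),
            class = "ncf_curve")
}

#' @export
print.ncf_curve <- function(x, ...) {
  cat(sprintf("NCF curve: k=%d marks (%s), %s, %d CSR samples\n",
              x$k, paste(x$marks, collapse = ","),
              if (x$cumulative) "cumulative" else "binned",
              x$n_csr_samples))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$r) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.ncf_curve <- function(x, ...) {
  data.frame(r = x$r, observed = x$observed_counts,
             expected = x$expected_counts, value = x$value,
             mc_stderr = x$mc_stderr)
}

#' @export
plot.ncf_curve <- function(x, ..., xlab = "r (um)", ylab = "NCF") {
  graphics::plot(x$r, x$value, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}

#' Write an NCF curve to CSV
#'
#' Columns: `r, observed, expected, value, mc_stderr`.
#'
#' @param curve An `"ncf_curve"`.
#' @param path Output file path.
#' @export
write_ncf <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
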