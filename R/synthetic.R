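#' Synthetic dataset I: mixed and segregated Thomas-type clusters
#'
#' A two-type clustered pattern on a 1000 x 1000 um domain designed so
#' that the two cell types colocalize on the left half and occupy
#' independent clusters on the right half:
#'
#' * Left half (`x < 500`): 20 cluster centers uniform in the left half;
#'   each receives 10 points of type C1 AND 10 of type C2 (shared
#'   centers), sampled from isotropic Gaussians.
#' * Right half: 10 cluster centers drawn independently PER type, 10
#'   points each.
#'
#' Every C2 point also carries a continuous mark `m`: uniform on
#' `[0, 0.5)` when the point's x-coordinate is below 500, uniform on
#' `[0.5, 1]` otherwise — so low marks tag cells in mixed clusters and
#' high marks cells in pure ones. C1 points carry `NA`. Gaussian samples
#' falling outside the domain are redrawn, so counts are exactly 300 per
#' type for any seed.
#'
#' @param seed Integer seed; the pattern is deterministic given the seed.
#' @param n_clusters_left,n_clusters_right Cluster-center counts (left:
#'   shared; right: per type).
#' @param points_per_cluster Points per type per cluster.
#' @param cluster_sd Gaussian standard deviation around centers (um).
#' @param domain The study rectangle.
#' @return A [point_pattern()] with marks `"C1"`, `"C2"` and continuous
#'   column `"m"`.
#' @export
generate_dataset_1 <- function(seed = NULL, n_clusters_left = 20,
                               n_clusters_right = 10,
                               points_per_cluster = 10, cluster_sd = 25,
                               domain = mxpcf::domain(0, 1000, 0, 1000)) {
  with_seed(seed, {
    half <- (domain$x_min + domain$x_max) / 2
    left <- mxpcf::domain(domain$x_min, half, domain$y_min, domain$y_max)
    right <- mxpcf::domain(half, domain$x_max, domain$y_min, domain$y_max)
    # shared centers on the left: both types around the same parents
    lc <- uniform_points(n_clusters_left, left)
    l1 <- gaussian_offspring(lc, points_per_cluster, cluster_sd, domain)
    l2 <- gaussian_offspring(lc, points_per_cluster, cluster_sd, domain)
    # independent centers per type on the right
    r1 <- gaussian_offspring(uniform_points(n_clusters_right, right),
                             points_per_cluster, cluster_sd, domain)
    r2 <- gaussian_offspring(uniform_points(n_clusters_right, right),
                             points_per_cluster, cluster_sd, domain)
    c1 <- rbind(l1, r1)
    c2 <- rbind(l2, r2)
    m2 <- ifelse(c2[, 1L] < half,
                 stats::runif(nrow(c2), 0, 0.5),
                 stats::runif(nrow(c2), 0.5, 1))
    point_pattern(c(c1[, 1L], c2[, 1L]), c(c1[, 2L], c2[, 2L]),
                  c(rep("C1", nrow(c1)), rep("C2", nrow(c2))),
                  domain,
                  continuous = data.frame(m = c(rep(NA_real_, nrow(c1)),
                                                m2)))
  })
}

#' Synthetic dataset II: pairwise vs three-way colocalization
#'
#' Three cell types A, B, C around three fixed cluster centers forming a
#' triangle of side ~300 um on a 1000 x 1000 um domain, in two variants
#' whose pairwise statistics match but whose three-way structure differs:
#'
#' * `"pairwise"`: cluster 1 holds 25 A + 25 B, cluster 2 holds 25 B +
#'   25 C, cluster 3 holds 25 A + 25 C — 50 points per type, every pair
#'   of types shares a cluster but no cluster contains all three.
#' * `"triplet"`: every cluster holds 25 of each type — 75 per type, all
#'   three types co-occur everywhere.
#'
#' Cross-PCFs of the two variants are statistically indistinguishable at
#' short range, while their neighbourhood correlation functions differ
#' sharply: with cluster spread 25 um and centers 300 um apart, no
#' all-three-type neighbourhood of radius below ~100 um exists in the
#' pairwise variant. Out-of-domain samples are redrawn so counts are
#' exact.
#'
#' @param seed Integer seed.
#' @param variant `"pairwise"` or `"triplet"`.
#' @param centers 3 x 2 matrix of cluster centers (um).
#' @param points_per_component Points per type per occupied cluster.
#' @param cluster_sd Gaussian standard deviation (um).
#' @param domain The study rectangle.
#' @return A [point_pattern()] with marks `"A"`, `"B"`, `"C"`.
#' @export
generate_dataset_2 <- function(seed = NULL,
                               variant = c("pairwise", "triplet"),
                               centers = rbind(c(350, 350), c(650, 350),
                                               c(500, 610)),
                               points_per_component = 25, cluster_sd = 25,
                               domain = mxpcf::domain(0, 1000, 0, 1000)) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(centers), nrow(centers) == 3L, ncol(centers) == 2L)
  # which types occupy which cluster
  occupancy <- if (variant == "pairwise") {
    list(`1` = c("A", "B"), `2` = c("B", "C"), `3` = c("A", "C"))
  } else {
    list(`1` = c("A", "B", "C"), `2` = c("A", "B", "C"),
         `3` = c("A", "B", "C"))
  }
  with_seed(seed, {
    xs <- ys <- numeric(0)
    marks <- character(0)
    for (k in 1:3) {
      for (type in occupancy[[k]]) {
        pts <- gaussian_offspring(centers[k, , drop = FALSE],
                                  points_per_component, cluster_sd, domain)
        xs <- c(xs, pts[, 1L]); ys <- c(ys, pts[, 2L])
        marks <- c(marks, rep(type, nrow(pts)))
      }
    }
    point_pattern(xs, ys, marks, domain)
  })
}

#' Complete spatial randomness pattern with fixed per-mark counts
#'
#' Draws each mark's points i.i.d. uniform on the domain with exactly the
#' requested count (a binomial process, i.e. a homogeneous Poisson
#' process conditioned on its count), matching how an observed pattern's
#' counts condition the CSR null.
#'
#' @param domain A [domain()].
#' @param counts_per_mark Named non-negative integer vector, e.g.
#'   `c(A = 100, B = 50)`.
#' @param seed Integer seed; same seed, same coordinates.
#' @return A [point_pattern()].
#' @examples
#' p <- generate_csr(domain(0, 1000, 0, 1000), c(A = 100), seed = 7)
#' @export
generate_csr <- function(domain, counts_per_mark, seed = NULL) {
  stopifnot(inherits(domain, "domain"))
  if (any(counts_per_mark < 0)) stop("counts must be non-negative")
  if (sum(counts_per_mark) < 1) stop("at least one point is required")
  with_seed(seed, csr_points(domain, counts_per_mark))
}

# n uniform points in a rectangle, as a matrix
uniform_points <- function(n, dom) {
  cbind(stats::runif(n, dom$x_min, dom$x_max),
        stats::runif(n, dom$y_min, dom$y_max))
}

# n_each Gaussian offspring around every center row; out-of-domain draws
# are redrawn (not clipped) so counts stay exact without boundary pile-up
gaussian_offspring <- function(centers, n_each, sd, dom) {
  n <- nrow(centers) * n_each
  cx <- rep(centers[, 1L], each = n_each)
  cy <- rep(centers[, 2L], each = n_each)
  x <- stats::rnorm(n, cx, sd)
  y <- stats::rnorm(n, cy, sd)
  bad <- !in_domain(x, y, dom)
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), cx[bad], sd)
    y[bad] <- stats::rnorm(sum(bad), cy[bad], sd)
    bad <- !in_domain(x, y, dom)
  }
  cbind(x, y)
}
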