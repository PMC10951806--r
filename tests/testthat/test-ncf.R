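test_that("tuple MEC radii match closed-form configurations", {
  d <- domain(0, 100, 0, 100)
  p <- point_pattern(c(10, 16), c(10, 10), c("A", "B"), d)
  expect_equal(triplet_mec_radii(p, c("A", "B"), r_max = 100), 3)
  # equilateral triangle, one point per mark -> circumradius
  tri <- point_pattern(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2),
                       c("A", "B", "C"), d)
  expect_equal(triplet_mec_radii(tri, c("A", "B", "C"), r_max = 10),
               1 / sqrt(3))
  # 2 x 2 x 2 tuples
  p8 <- point_pattern(runif(6, 40, 60), runif(6, 40, 60),
                      rep(c("A", "B", "C"), each = 2), d)
  expect_length(triplet_mec_radii(p8, c("A", "B", "C"), r_max = 1000), 8)
  expect_error(triplet_mec_radii(p8, "A", r_max = 10), "at least two")
  expect_error(triplet_mec_radii(p8, c("A", "Z"), r_max = 10),
               "not present")
})

test_that("pairwise-distance pruning leaves the retained radii unchanged", {
  set.seed(31)
  d <- domain(0, 200, 0, 200)
  p <- point_pattern(runif(18, 0, 200), runif(18, 0, 200),
                     rep(c("A", "B", "C"), each = 6), d)
  r_max <- 40
  pruned <- sort(triplet_mec_radii(p, c("A", "B", "C"), r_max = r_max))
  # oracle: enumerate every tuple with the generic MEC, no prefilter
  ca <- mark_coords(p, "A"); cb <- mark_coords(p, "B")
  cc <- mark_coords(p, "C")
  full <- c()
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    full <- c(full,
              brute_mec(rbind(ca[i, ], cb[j, ], cc[k, ]))$radius)
  }
  expect_equal(pruned, sort(full[full <= r_max]), tolerance = 1e-9)
})

test_that("duplicate coordinates across marks give a radius-0 tuple", {
  d <- domain(0, 10, 0, 10)
  p <- point_pattern(c(5, 5, 5), c(5, 5, 5), c("A", "B", "C"), d)
  expect_equal(triplet_mec_radii(p, c("A", "B", "C"), r_max = 10), 0)
})

test_that("CSR MEC distribution has the right endpoints and pair oracle", {
  d <- domain(0, 1000, 0, 1000)
  g <- radial_grid(r_max = 800, dr = 100, width = 100)
  null <- csr_mec_probability(d, k = 3, grid = g, n_samples = 2e4,
                              seed = 6)
  expect_equal(min(null$cum_prob[null$r == 0]), null$cum_prob[1])
  # every tuple fits inside a circle of half the domain diagonal
  expect_equal(null$cum_prob[length(null$cum_prob)], 1)
  expect_true(all(diff(null$cum_prob) >= 0))
  # k = 2: MEC radius <= r  <=>  pair distance <= 2r; closed-form CDF of
  # the uniform-square distance distribution is the independent oracle
  g2 <- radial_grid(r_max = 400, dr = 50, width = 50)
  null2 <- csr_mec_probability(d, k = 2, grid = g2, n_samples = 4e4,
                               seed = 7)
  for (b in seq_along(g2$r)) {
    t_up <- 2 * (g2$r[b] + g2$width) / 1000
    expected <- unit_square_dist_cdf(t_up)
    se <- sqrt(expected * (1 - expected) / null2$n_samples)
    expect_lt(abs(null2$cum_prob[b] - expected), 3 * se + 1e-6)
  }
})

test_that("CSR MEC sampling is deterministic given the seed", {
  d <- domain(0, 100, 0, 100)
  g <- radial_grid(r_max = 100, dr = 20, width = 20)
  a <- csr_mec_probability(d, k = 3, grid = g, n_samples = 5e3, seed = 3)
  b <- csr_mec_probability(d, k = 3, grid = g, n_samples = 5e3, seed = 3)
  expect_identical(a$prob, b$prob)
})

test_that("NCF calibrates to 1 on three independent CSR marks", {
  d <- domain(0, 1000, 0, 1000)
  p <- generate_csr(d, c(A = 100, B = 100, C = 100), seed = 8)
  curve <- ncf(p, c("A", "B", "C"), radial_grid(r_max = 300),
               n_samples = 5e4, seed = 9)
  well <- which(curve$expected_counts > 100)
  expect_gt(length(well), 5)
  expect_lt(abs(mean(curve$value[well]) - 1), 0.15)
})

test_that("NCF separates the two dataset II variants", {
  g <- radial_grid(r_max = 300)
  pw <- ncf(generate_dataset_2(seed = 0, variant = "pairwise"),
            c("A", "B", "C"), g, n_samples = 5e4, seed = 1)
  tr <- ncf(generate_dataset_2(seed = 0, variant = "triplet"),
            c("A", "B", "C"), g, n_samples = 5e4, seed = 1)
  # pairwise-only structure: no three-type neighbourhood below the
  # inter-cluster scale
  low <- pw$r + pw$grid$width <= 100
  expect_true(all(pw$observed_counts[low] == 0))
  expect_true(all(pw$value[low] == 0, na.rm = TRUE))
  # and it rises towards 1 beyond it
  expect_gt(max(pw$value[pw$r >= 150], na.rm = TRUE), 0.5)
  # triplet structure: strong short-range three-way correlation
  expect_gt(max(tr$value[tr$r <= 50], na.rm = TRUE), 10)
})

test_that("zero-expectation bins are missing, never zero", {
  d <- domain(0, 5000, 0, 5000)
  p <- point_pattern(c(10, 12, 14), c(10, 10, 10), c("A", "B", "C"), d)
  # tiny radii bins: CSR samples essentially never land there
  curve <- ncf(p, c("A", "B", "C"), radial_grid(r_max = 10, dr = 2,
                                                width = 2),
               n_samples = 100, seed = 2)
  expect_true(all(is.na(curve$value[curve$expected_counts == 0])))
})

test_that("cumulative NCF counts are non-decreasing and consistent", {
  p <- generate_dataset_2(seed = 5, variant = "triplet")
  g <- radial_grid(r_max = 200)
  cum <- ncf(p, c("A", "B", "C"), g, n_samples = 2e4, seed = 3,
             cumulative = TRUE)
  expect_true(all(diff(cum$observed_counts) >= 0))
  expect_true(all(diff(cum$expected_counts) >= -1e-9))
  binned <- ncf(p, c("A", "B", "C"), g, n_samples = 2e4, seed = 3)
  expect_equal(cumsum(binned$observed_counts), cum$observed_counts)
})

test_that("NCF generalizes beyond three marks", {
  set.seed(33)
  d <- domain(0, 200, 0, 200)
  p <- point_pattern(runif(20, 0, 200), runif(20, 0, 200),
                     rep(c("A", "B", "C", "D"), 5), d)
  radii <- triplet_mec_radii(p, c("A", "B", "C", "D"), r_max = 1000)
  expect_length(radii, 5^4)
  # spot-check one tuple against the exhaustive oracle
  ca <- mark_coords(p, "A")[1, ]; cb <- mark_coords(p, "B")[1, ]
  cc <- mark_coords(p, "C")[1, ]; cd <- mark_coords(p, "D")[1, ]
  ref <- brute_mec(rbind(ca, cb, cc, cd))$radius
  expect_true(any(abs(radii - ref) < 1e-9))
})
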