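test_that("triangular weighting kernel has unit peak, midpoint and support", {
  expect_equal(mark_weight(0.3, 0.3, delta = 0.1), 1)
  expect_equal(mark_weight(0.35, 0.3, delta = 0.1), 0.5)
  expect_equal(mark_weight(0.41, 0.3, delta = 0.1), 0)
  expect_equal(mark_weight(0.19, 0.3, delta = 0.1), 0)
  expect_equal(mark_weight(NA, 0.3, delta = 0.1), 0)
  expect_error(mark_weight(0.3, 0.3, delta = 0), "positive")
  # gaussian option keeps the unit peak but has unbounded support
  expect_equal(mark_weight(0.3, 0.3, delta = 0.1, kernel = "gaussian"), 1)
  expect_gt(mark_weight(0.6, 0.3, delta = 0.1, kernel = "gaussian"), 0)
})

test_that("wPCF reproduces the hand-evaluated weighted pair", {
  d <- domain(0, 100, 0, 100)
  p <- point_pattern(c(50, 50), c(50, 58), c("C", "X"), d,
                     continuous = data.frame(v = c(NA, 0.7)))
  # single partner at weight 0.5: the weight cancels through W_M
  surf <- wpcf(p, "C", "v", targets = 0.75, delta = 0.1,
               grid = radial_grid(r_max = 10, dr = 10))
  expect_equal(as.numeric(surf$values), 1e4 / (100 * pi))
})

test_that("wPCF matches the brute-force double-loop oracle", {
  set.seed(41)
  g <- radial_grid(r_max = 45, dr = 15, width = 15)
  targets <- c(0.2, 0.5, 0.8)
  for (rep in 1:3) {
    p <- random_pattern(sample(12:30, 1), with_continuous = TRUE)
    surf <- wpcf(p, "A", "m", targets = targets, grid = g, delta = 0.25)
    expect_equal(surf$values, brute_wpcf(p, "A", "m", targets, g, 0.25))
  }
})

test_that("degenerate continuous marks reduce the wPCF to a cross-PCF", {
  set.seed(42)
  d <- domain(0, 200, 0, 200)
  n <- 40
  x <- runif(n, 0, 200); y <- runif(n, 0, 200)
  marks <- rep(c("C", "P"), n / 2)
  # all partner marks identically 0.6: the row at M = 0.6 must equal the
  # cross-PCF against all points (weights are 1 for every point)
  m <- rep(0.6, n)
  p <- point_pattern(x, y, marks, d, continuous = data.frame(m = m))
  g <- radial_grid(r_max = 60, dr = 20)
  surf <- wpcf(p, "C", "m", targets = 0.6, grid = g, delta = 0.2)
  # oracle: same pattern, all points relabelled into one partner class,
  # plus the centers duplicated so the cross-PCF j-sum covers ALL points.
  # Direct double-loop is simpler and fully independent:
  expect_equal(as.numeric(surf$values),
               brute_wpcf(p, "C", "m", 0.6, g, 0.2)[1, ])
})

test_that("binary-concentrated marks recover hard-classified cross-PCFs", {
  set.seed(43)
  d <- domain(0, 300, 0, 300)
  nC <- 30; nL <- 25; nH <- 25
  x <- runif(nC + nL + nH, 0, 300); y <- runif(nC + nL + nH, 0, 300)
  marks <- c(rep("C", nC), rep("L", nL), rep("H", nH))
  m <- c(rep(NA, nC), rep(0, nL), rep(1, nH))
  p <- point_pattern(x, y, marks, d, continuous = data.frame(m = m))
  g <- radial_grid(r_max = 80, dr = 20)
  # delta below the gap between the two mark levels: weights are exactly
  # the class indicators, so each row is the corresponding cross-PCF
  surf <- wpcf(p, "C", "m", targets = c(0, 1), grid = g, delta = 0.4)
  expect_equal(surf$values[1, ], cross_pcf(p, "C", "L", g)$value)
  expect_equal(surf$values[2, ], cross_pcf(p, "C", "H", g)$value)
})

test_that("wPCF is invariant under affine rescaling of the mark", {
  set.seed(44)
  p <- random_pattern(30, with_continuous = TRUE)
  g <- radial_grid(r_max = 40, dr = 20)
  targets <- c(0.25, 0.75)
  ref <- wpcf(p, "A", "m", targets = targets, grid = g, delta = 0.2)
  p2 <- p
  p2$continuous$m <- 10 + 5 * p$continuous$m
  scaled <- wpcf(p2, "A", "m", targets = 10 + 5 * targets, grid = g,
                 delta = 5 * 0.2)
  expect_equal(scaled$values, ref$values)
})

test_that("dataset I wPCF splits clustering and exclusion at the mark gap", {
  p <- generate_dataset_1(seed = 2)
  g <- radial_grid(r_max = 60, dr = 10)
  surf <- wpcf(p, "C1", "m", targets = c(0.25, 0.75), grid = g,
               delta = 0.1)
  # low marks tag C2 cells in mixed clusters: strong short-range clustering
  expect_gt(surf$values[1, 1], 2)
  # high marks tag segregated clusters: weak exclusion at the smallest radii
  expect_lt(surf$values[2, 1], 1)
})

test_that("zero-weight targets are missing and missing columns error", {
  d <- domain(0, 100, 0, 100)
  p <- point_pattern(c(10, 50), c(10, 50), c("C", "P"), d,
                     continuous = data.frame(v = c(NA, 0.5)))
  surf <- wpcf(p, "C", "v", targets = c(0.5, 99), delta = 0.1,
               grid = radial_grid(r_max = 20, dr = 10))
  expect_true(all(is.na(surf$values[2, ])))
  expect_false(anyNA(surf$values[1, ]))
  expect_error(wpcf(p, "C", "nope"), "not present")
})

test_that("two-continuous-mark wPCF reduces to the one-mark form", {
  set.seed(45)
  d <- domain(0, 200, 0, 200)
  n <- 30
  x <- runif(n, 0, 200); y <- runif(n, 0, 200)
  # column c1 degenerate at 1 for the "center" half, NA otherwise mirrors
  # a categorical selection; column c2 is a genuine continuous mark
  centers <- rep(c(TRUE, FALSE), n / 2)
  c1 <- ifelse(centers, 1, NA)
  c2 <- runif(n)
  p <- point_pattern(x, y, ifelse(centers, "C", "P"), d,
                     continuous = data.frame(c1 = c1, c2 = c2))
  g <- radial_grid(r_max = 60, dr = 20)
  targets2 <- c(0.3, 0.7)
  two <- wpcf_continuous(p, "c1", "c2", targets_1 = 1,
                         targets_2 = targets2, grid = g,
                         delta_1 = 0.5, delta_2 = 0.2)
  one <- wpcf(p, "C", "c2", targets = targets2, grid = g, delta = 0.2)
  expect_equal(two$values[1, , ], one$values)
})

test_that("wPCF of position-independent marks calibrates to 1", {
  set.seed(46)
  d <- domain(0, 1000, 0, 1000)
  p <- generate_csr(d, c(A = 500), seed = 11)
  p$continuous <- data.frame(m = runif(500))
  g <- radial_grid(r_start = 20, r_max = 200, dr = 20)
  surf <- wpcf(p, "A", "m", targets = c(0.3, 0.5, 0.7), grid = g,
               delta = 0.2)
  expect_lt(max(abs(surf$values - 1)), 0.35)
  expect_lt(abs(mean(surf$values) - 1), 0.1)
})

test_that("a single-point pattern yields an all-missing two-mark surface", {
  d <- domain(0, 100, 0, 100)
  p <- point_pattern(50, 50, "A", d,
                     continuous = data.frame(u = 0.5, v = 0.5))
  surf <- wpcf_continuous(p, "u", "v", targets_1 = 0.5, targets_2 = 0.5,
                          grid = radial_grid(r_max = 20, dr = 10),
                          delta_1 = 0.1, delta_2 = 0.1)
  expect_true(all(is.na(surf$values)))
})
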