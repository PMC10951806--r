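#' CSR simulation envelope for a correlation statistic
#'
#' Simulates complete spatial randomness (CSR) patterns with the given
#' per-mark counts on the domain, evaluates a statistic on each and
#' returns pointwise empirical quantiles. Observed curves falling outside
#' the envelope at some radius indicate departure from CSR at that scale
#' (pointwise, not corrected for simultaneous inference).
#'
#' @param domain A [domain()].
#' @param counts_per_mark Named integer vector: points per categorical
#'   mark in each simulated pattern.
#' @param statistic Either a function `pattern -> "correlation_curve"`,
#'   or a list configuration such as
#'   `list(name = "pcf", mark = "A", grid = radial_grid())` or
#'   `list(name = "cross_pcf", mark_a = "A", mark_b = "B", grid = ...)`.
#' @param n_sims Number of CSR simulations, `>= 19`.
#' @param quantiles Lower and upper envelope probabilities.
#' @param seed Integer seed; the envelope is deterministic given the seed.
#' @param observed Optional observed `"correlation_curve"`; if supplied,
#'   the fraction of radii at which it falls inside the envelope is
#'   reported as `coverage`.
#' @return A list of class `"csr_envelope"` with `r`, `lo`, `hi`,
#'   `n_sims`, `quantiles`, and (if `observed` was given) `observed` and
#'   `coverage`.
#' @examples
#' d <- domain(0, 500, 0, 500)
#' env <- csr_envelope(d, c(A = 100),
#'                     list(name = "pcf", mark = "A",
#'                          grid = radial_grid(r_max = 100)),
#'                     n_sims = 19, seed = 1)
#' @export
csr_envelope <- function(domain, counts_per_mark, statistic,
                         n_sims = 99, quantiles = c(0.025, 0.975),
                         seed = NULL, observed = NULL) {
  stopifnot(inherits(domain, "domain"))
  if (n_sims < 19) stop("n_sims must be at least 19")
  if (any(counts_per_mark <= 0)) stop("per-mark counts must be positive")
  if (length(quantiles) != 2L || any(quantiles < 0) || any(quantiles > 1) ||
      quantiles[1L] >= quantiles[2L]) {
    stop("quantiles must be an increasing pair of probabilities")
  }
  stat_fun <- make_statistic(statistic)
  curves <- with_seed(seed, {
    lapply(seq_len(n_sims), function(s) {
      p <- csr_points(domain, counts_per_mark)
      stat_fun(p)
    })
  })
  r <- curves[[1L]]$r
  vals <- do.call(rbind, lapply(curves, `[[`, "value"))
  lo <- apply(vals, 2L, stats::quantile, probs = quantiles[1L],
              na.rm = TRUE, names = FALSE)
  hi <- apply(vals, 2L, stats::quantile, probs = quantiles[2L],
              na.rm = TRUE, names = FALSE)
  out <- structure(list(r = r, lo = lo, hi = hi, n_sims = n_sims,
                        quantiles = quantiles),
                   class = "csr_envelope")
  if (!is.null(observed)) {
    stopifnot(inherits(observed, "correlation_curve"))
    if (!isTRUE(all.equal(observed$r, r))) {
      stop("observed curve evaluated on a different radial grid")
    }
    inside <- observed$value >= lo & observed$value <= hi
    out$observed <- observed$value
    out$coverage <- mean(inside, na.rm = TRUE)
  }
  out
}

# turn a statistic configuration into pattern -> curve
make_statistic <- function(statistic) {
  if (is.function(statistic)) return(statistic)
  if (is.list(statistic) && !is.null(statistic$name)) {
    grid <- if (is.null(statistic$grid)) radial_grid() else statistic$grid
    return(switch(statistic$name,
      pcf = function(p) pcf(p, statistic$mark, grid),
      cross_pcf = function(p) cross_pcf(p, statistic$mark_a,
                                        statistic$mark_b, grid),
      stop(sprintf("unknown statistic '%s'", statistic$name))
    ))
  }
  stop("statistic must be a function or a named configuration list")
}

# CSR pattern draw using the current RNG stream (no reseeding)
csr_points <- function(dom, counts_per_mark) {
  labs <- names(counts_per_mark)
  if (is.null(labs)) stop("counts_per_mark must be named by mark")
  x <- y <- numeric(0)
  marks <- character(0)
  for (lab in labs) {
    n <- counts_per_mark[[lab]]
    x <- c(x, stats::runif(n, dom$x_min, dom$x_max))
    y <- c(y, stats::runif(n, dom$y_min, dom$y_max))
    marks <- c(marks, rep(lab, n))
  }
  point_pattern(x, y, marks, dom)
}

#' @export
print.csr_envelope <- function(x, ...) {
  cat(sprintf("CSR envelope: %d simulations, quantiles (%g, %g), %d radii\n",
              x$n_sims, x$quantiles[1L], x$quantiles[2L], length(x$r)))
  if (!is.null(x$coverage)) {
    cat(sprintf("observed curve inside envelope at %.1f%% of radii\n",
                100 * x$coverage))
  }
  invisible(x)
}

#' @export
plot.csr_envelope <- function(x, ..., xlab = "r (um)", ylab = "statistic") {
  ylim <- range(c(x$lo, x$hi, x$observed), na.rm = TRUE)
  graphics::plot(x$r, x$hi, type = "n", ylim = ylim,
                 xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$r, rev(x$r)), c(x$lo, rev(x$hi)),
                    col = "grey85", border = NA)
  if (!is.null(x$observed)) graphics::lines(x$r, x$observed, lwd = 2)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}
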