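#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so that library internals never perturb
#' user-level random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Centered moving average with truncated edge windows.
rolling_mean <- function(x, window) {
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + (window - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Least-squares Gaussian fit to a frequency histogram
#'
#' Bins `values` and fits an unnormalised Gaussian curve to the histogram by
#' non-linear least squares.  Compared with moment estimation this is robust
#' to the heavy right tails produced by repetitive regions in depth data.
#' Falls back to moment estimates if the curve fit does not converge.
#'
#' @param values Numeric vector of observations.
#' @param binwidth Histogram bin width; when `NULL` roughly 100 bins are used.
#' @return List with elements `mean` and `sd`.
#' @keywords internal
fit_gaussian_histogram <- function(values, binwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("cannot fit a distribution to fewer than 2 values")
  m0 <- mean(values)
  s0 <- stats::sd(values)
  if (!is.finite(s0) || s0 <= 0) stop("degenerate distribution: all values equal")
  if (is.null(binwidth)) binwidth <- diff(range(values)) / 100
  breaks <- seq(floor(min(values) / binwidth) * binwidth - binwidth / 2,
                max(values) + binwidth, by = binwidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$density
  keep <- y > 0 | (x > m0 - 4 * s0 & x < m0 + 4 * s0)
  x <- x[keep]; y <- y[keep]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * sg^2)),
      start = list(a = max(y), mu = m0, sg = s0),
      lower = c(a = 0, mu = -Inf, sg = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    list(mean = m0, sd = s0)
  } else {
    cf <- stats::coef(fit)
    list(mean = unname(cf["mu"]), sd = abs(unname(cf["sg"])))
  }
}

# Sorted multiset helpers used by genotype and path modules ------------------

multiset_key <- function(x) paste(sort(x), collapse = "\r")

multiset_diff <- function(x, y) {
  for (a in y) {
    i <- match(a, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}

multiset_intersect <- function(x, y) {
  out <- character(0)
  for (a in x) {
    i <- match(a, y)
    if (!is.na(i)) {
      out <- c(out, a)
      y <- y[-i]
    }
  }
  out
}
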