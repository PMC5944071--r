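test_that("depth distribution recovers simulated per-copy parameters", {
  depth <- with_seed(101, round(rnorm(1e6, 50, 6)))
  d <- fit_depth_distribution(list(chr1 = depth), ploidy = 2)
  expect_lt(abs(d$mean - 25), 0.5)
  expect_lt(abs(d$sd - 3), 0.5)

  # per-copy scaling: a copy_number=4 region at doubled true depth gives the
  # same per-copy fit
  depth2 <- depth
  depth2[1:2e5] <- with_seed(102, round(rnorm(2e5, 100, 12)))
  cn <- data.frame(chrom = "chr1", start = 0L, end = 2e5L, copy_number = 4L)
  d2 <- fit_depth_distribution(list(chr1 = depth2), ploidy = 2,
                               copy_number_map = cn)
  expect_lt(abs(d2$mean - 25), 0.5)
  expect_lt(abs(d2$sd - 3), 0.5)

  expect_error(fit_depth_distribution(list(chr1 = rep(50, 100)), ploidy = 2),
               "degenerate")
})

test_that("abnormal-region detection finds planted excursions and honors merge distance", {
  dist <- structure(list(mean = 25, sd = 1.5), class = "depth_distribution")

  flat <- list(chr1 = rep(50, 5000))
  expect_equal(nrow(detect_abnormal_regions(flat, dist, ploidy = 2)), 0L)

  # planted 300-bp segment at 3x the mean
  depth <- with_seed(103, round(rnorm(20000, 50, 3)))
  depth[8001:8300] <- round(depth[8001:8300] * 3)
  regions <- detect_abnormal_regions(list(chr1 = depth), dist, ploidy = 2)
  overlaps <- regions$start < 8300 & regions$end > 8000
  expect_equal(sum(overlaps), 1L)
  expect_true(all(overlaps))
  expect_equal(regions$side[overlaps], "high")

  # two low spikes: merged within 1000 bp, separate beyond
  mk <- function(gap) {
    d <- rep(50, 10000)
    d[2001:2060] <- 10
    d[(2060 + gap + 1):(2060 + gap + 60)] <- 10
    detect_abnormal_regions(list(chr1 = d), dist, ploidy = 2)
  }
  expect_equal(nrow(mk(1500)), 2L)
  expect_equal(nrow(mk(800)), 1L)

  expect_error(detect_abnormal_regions(flat, dist, ploidy = 2, window = 0),
               "window")
})

test_that("abnormal regions are rare on tracks drawn from the fitted null", {
  # expected significant windows ~ n * 1e-4; regions should be near zero
  n_regions <- vapply(1:5, function(s) {
    depth <- with_seed(110 + s, round(rnorm(50000, 50, 6)))
    d <- fit_depth_distribution(list(chr1 = depth), ploidy = 2)
    nrow(detect_abnormal_regions(list(chr1 = depth), d, ploidy = 2))
  }, numeric(1))
  expect_lte(mean(n_regions > 0), 0.6)  # loose: windows are correlated
})

test_that("strand-bias distribution recovers simulated log-ratio spread", {
  # balanced strands with binomial noise only: mean ~ 0
  tot <- 200L
  lr <- with_seed(104, rnorm(20000, 0, 0.4))
  top <- round(tot * exp(lr) / (1 + exp(lr)))
  b <- fit_strand_bias_distribution(top, tot - top)
  expect_lt(abs(b$mean), 0.02)
  expect_lt(abs(b$sd - 0.4) / 0.4, 0.1)

  balanced <- with_seed(105, rbinom(20000, 100, 0.5))
  b2 <- fit_strand_bias_distribution(balanced, 100 - balanced)
  expect_lt(abs(b2$mean), 0.02)

  expect_error(fit_strand_bias_distribution(5L, 5L), "fewer than 2")
})

test_that("strand-bias p-values are symmetric, tail-correct and monotone", {
  d <- structure(list(mean = 0, sd = 0.3), class = "strand_bias_distribution")
  expect_equal(strand_bias_p_value(20, 20, d), 1)
  expect_lt(strand_bias_p_value(40, 0, d), 1e-6)
  # closed-form check
  lr <- log(41 / 1)
  expect_equal(strand_bias_p_value(40, 0, d),
               2 * pnorm(lr, 0, 0.3, lower.tail = FALSE))
  # monotone decreasing in |ln ratio - mean|
  ps <- strand_bias_p_value(c(20, 25, 30, 35, 40), c(20, 15, 10, 5, 0), d)
  expect_true(all(diff(ps) < 0))
})

test_that("chromosome-end depth correction recovers planted bias and is idempotent", {
  # the genome must be long relative to the biased ends, else the global
  # mean itself absorbs part of the bias and shifts the ratio intercept
  true <- list(intercept = 1, scalar = 1.5, mu = log(5000), sigma = 0.5,
               slope = 0)
  L <- 1000000L
  pos <- seq_len(L)
  x <- pmin(pos, L - pos + 1L)
  factor_true <- depth_correction_factor(true, x)
  depth <- with_seed(106, 50 * factor_true * rnorm(L, 1, 0.03))
  track <- list(chr1 = depth)
  fit <- fit_depth_correction(track)
  expect_lt(abs(fit$scalar - 1.5) / 1.5, 0.15)
  expect_lt(abs(fit$mu - log(5000)) / log(5000), 0.15)
  expect_lt(abs(fit$sigma - 0.5) / 0.5, 0.15)
  expect_lt(abs(fit$intercept - 1), 0.05)

  corrected <- correct_depths(track, fit)
  gm <- mean(corrected$chr1)
  bin <- (x - 1L) %/% 500L
  med <- tapply(corrected$chr1 / gm, bin, median)
  expect_true(all(med > 0.95 & med < 1.05))

  refit <- fit_depth_correction(corrected)
  expect_lt(refit$scalar, 0.1)

  # unbiased track: scalar ~ 0, slope ~ 0, intercept ~ 1
  flat <- list(chr1 = with_seed(107, 50 * rnorm(2e5, 1, 0.03)))
  f0 <- fit_depth_correction(flat)
  expect_lt(abs(f0$intercept - 1), 0.05)
  expect_lt(f0$scalar, 0.05)
  expect_lt(abs(f0$slope), 1e-4)
})

test_that("extreme depth ratios are excluded from bin medians", {
  L <- 20000L
  depth <- rep(50, L)
  # plant outliers that would drag the first bin median above 4x
  depth[1:400] <- 500
  fit <- fit_depth_correction(list(chr1 = depth))
  first_bin <- fit$bins$median_ratio[fit$bins$x == 250]
  expect_lt(first_bin, 4)
})

test_that("depth correction with unit factor is the identity and preserves zeros", {
  ident <- list(intercept = 1, scalar = 0, mu = 0, sigma = 1, slope = 0)
  track <- list(chr1 = c(0, 10, 20, 0, 30))
  out <- correct_depths(track, ident)
  expect_equal(out, track)
  biased <- list(intercept = 0.5, scalar = 1, mu = log(2), sigma = 0.5,
                 slope = 0)
  out2 <- correct_depths(track, biased)
  expect_equal(out2$chr1[c(1, 4)], c(0, 0))
})
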