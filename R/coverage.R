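#' Fit the per-sample depth-of-coverage distribution
#'
#' Depths are divided by the local copy number (from `copy_number_map` when
#' provided, else the sample ploidy) and a Gaussian is fit by least squares
#' to the integer-binned frequency histogram of the per-copy depths.  The
#' histogram fit, rather than moment estimation, keeps the parameters robust
#' to the heavy right tail contributed by repetitive regions.
#'
#' @param track Depth track: named list of per-position numeric vectors.
#' @param ploidy Sample ploidy (default copy number).
#' @param copy_number_map Optional data frame `chrom`, `start`, `end`
#'   (0-based half-open), `copy_number` overriding ploidy locally.
#' @return Object of class `depth_distribution` with elements `mean` and
#'   `sd` of the per-copy depth.
#' @export
fit_depth_distribution <- function(track, ploidy, copy_number_map = NULL) {
  values <- unlist(lapply(names(track), function(chrom) {
    track[[chrom]] / copy_number_vector(chrom, length(track[[chrom]]),
                                        ploidy, copy_number_map)
  }), use.names = FALSE)
  if (length(values) == 0L) stop("empty depth track")
  fit <- fit_gaussian_histogram(values, binwidth = 1)
  structure(list(mean = fit$mean, sd = fit$sd), class = "depth_distribution")
}

copy_number_vector <- function(chrom, len, ploidy, copy_number_map = NULL) {
  cn <- rep(as.numeric(ploidy), len)
  if (!is.null(copy_number_map)) {
    m <- copy_number_map[copy_number_map$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(m))) {
      lo <- max(m$start[i] + 1L, 1L)
      hi <- min(m$end[i], len)
      if (lo <= hi) cn[lo:hi] <- m$copy_number[i]
    }
  }
  cn
}

#' Detect regions of abnormal sequencing depth
#'
#' Per-position per-copy depths are averaged with a centered moving window
#' (truncated at chromosome edges) and compared against the fitted Gaussian
#' CDF, giving a two-tailed p-value per position.  Significant positions on
#' the same side of the mean that fall within `merge_distance` of one
#' another bound a region; each region spans its first through last
#' significant position.
#'
#' @param track Depth track.
#' @param distribution A [fit_depth_distribution()] result.
#' @param ploidy Sample ploidy.
#' @param copy_number_map Optional copy-number override map.
#' @param window Moving-average window in bp (default 25).
#' @param p_threshold Two-tailed p-value threshold (default 1e-4).
#' @param merge_distance Maximum distance between significant positions
#'   merged into one region (default 1000 bp).
#' @return A `data.frame` of regions in BED convention: `chrom`, `start`
#'   (0-based), `end` (half-open), and `side` (`"high"`/`"low"`).
#' @export
detect_abnormal_regions <- function(track, distribution, ploidy,
                                    copy_number_map = NULL, window = 25L,
                                    p_threshold = 1e-4,
                                    merge_distance = 1000L) {
  if (window < 1L) stop("window must be >= 1")
  out <- lapply(names(track), function(chrom) {
    d <- track[[chrom]] / copy_number_vector(chrom, length(track[[chrom]]),
                                             ploidy, copy_number_map)
    avg <- rolling_mean(d, window)
    p <- 2 * pmin(stats::pnorm(avg, distribution$mean, distribution$sd),
                  stats::pnorm(avg, distribution$mean, distribution$sd,
                               lower.tail = FALSE))
    sig <- which(p < p_threshold)
    if (!length(sig)) return(NULL)
    side <- avg[sig] > distribution$mean
    newgrp <- c(TRUE, diff(sig) > merge_distance | side[-1] != side[-length(side)])
    grp <- cumsum(newgrp)
    starts <- tapply(sig, grp, min)
    ends <- tapply(sig, grp, max)
    sides <- tapply(side, grp, `[`, 1L)
    data.frame(chrom = chrom, start = as.integer(starts) - 1L,
               end = as.integer(ends),
               side = ifelse(sides, "high", "low"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), side = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Fit the per-sample strand-bias distribution
#'
#' For each position with at least one read, the natural log of the ratio of
#' top- to bottom-strand counts is computed after adding a pseudo-count of 1
#' to each strand (so single-strand positions remain usable), and a Gaussian
#' is fit to the frequency histogram of the log ratios.
#'
#' @param top,bottom Integer vectors of per-position strand counts.
#' @return Object of class `strand_bias_distribution` with `mean` and `sd`.
#' @export
fit_strand_bias_distribution <- function(top, bottom) {
  stopifnot(length(top) == length(bottom))
  keep <- (top + bottom) >= 1
  lr <- log((top[keep] + 1) / (bottom[keep] + 1))
  if (length(lr) < 2L) stop("cannot fit strand bias: fewer than 2 usable positions")
  if (stats::sd(lr) == 0) stop("degenerate strand-bias distribution")
  fit <- fit_gaussian_histogram(lr)
  structure(list(mean = fit$mean, sd = fit$sd),
            class = "strand_bias_distribution")
}

#' Two-tailed strand-bias p-value
#'
#' Standardises `ln((top + 1) / (bottom + 1))` against the genome-wide
#' strand-bias distribution and returns `2 * min(lower, upper)` Gaussian
#' tail probabilities.  Vectorised over positions.
#'
#' @param top,bottom Strand counts (`top + bottom > 0`).
#' @param distribution A [fit_strand_bias_distribution()] result.
#' @return Two-tailed p-values in (0, 1].
#' @export
strand_bias_p_value <- function(top, bottom, distribution) {
  lr <- log((top + 1) / (bottom + 1))
  lo <- stats::pnorm(lr, distribution$mean, distribution$sd)
  pmin(2 * pmin(lo, 1 - lo), 1)
}

#' Fit the chromosome-end depth-bias correction model
#'
#' Sequencing depth is often inflated near chromosome ends.  The expected
#' depth relative to the genomic mean, as a function of the distance `x`
#' (bp) to the nearest chromosome end, is modelled as the sum of a
#' complementary log-normal CDF and a linear term:
#' `factor(x) = scalar * (1 - plnorm(x, mu, sigma)) + intercept + slope * x`.
#' Per-position depth ratios (depth over global mean) are placed in
#' `bin_size`-bp bins of `x`; bin medians, after excluding extreme ratios
#' above 4 or below 0.25, are fit by non-linear least squares.
#'
#' @param track Depth track.
#' @param bin_size Bin width in bp (default 500).
#' @return Object of class `depth_correction_model` with `intercept`,
#'   `scalar`, `mu`, `sigma`, `slope`, plus the binned medians used.
#' @export
fit_depth_correction <- function(track, bin_size = 500L) {
  gm <- mean(unlist(track, use.names = FALSE))
  if (!is.finite(gm) || gm <= 0) stop("cannot fit depth correction: zero mean depth")
  xs <- list(); ys <- list()
  for (chrom in names(track)) {
    v <- track[[chrom]]
    L <- length(v)
    pos <- seq_len(L)
    d <- pmin(pos, L - pos + 1L)
    ratio <- v / gm
    keep <- ratio <= 4 & ratio >= 0.25
    xs[[chrom]] <- d[keep]
    ys[[chrom]] <- ratio[keep]
  }
  d <- unlist(xs, use.names = FALSE)
  ratio <- unlist(ys, use.names = FALSE)
  bin <- (d - 1L) %/% bin_size
  med <- tapply(ratio, bin, stats::median)
  x <- (as.numeric(names(med)) + 0.5) * bin_size
  y <- as.numeric(med)
  if (length(x) < 10L) stop("cannot fit depth correction: fewer than 10 usable bins")
  far <- x >= stats::quantile(x, 0.5)
  intercept0 <- stats::median(y[far])
  scalar0 <- max(max(y) - intercept0, 0.01)
  half <- intercept0 + scalar0 / 2
  cross <- x[which(y <= half)[1]]
  mu0 <- log(ifelse(is.na(cross) || cross <= 0, stats::median(x), cross))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ scalar * (1 - stats::plnorm(x, mu, sigma)) + intercept + slope * x,
      start = list(intercept = intercept0, scalar = scalar0, mu = mu0,
                   sigma = 0.5, slope = 0),
      lower = c(intercept = -Inf, scalar = 0, mu = -Inf, sigma = 1e-3,
                slope = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    if (diff(range(y)) < 0.1) {
      # no end-bias signal: the profile is flat and the log-normal component
      # is unidentifiable; reduce to the linear part
      lin <- stats::lm(y ~ x)
      cf <- list(intercept = unname(stats::coef(lin)[1]), scalar = 0,
                 mu = log(stats::median(x)), sigma = 0.5,
                 slope = unname(stats::coef(lin)[2]))
    } else {
      stop("depth-correction fit failed to converge: ",
           conditionMessage(fit), " [", length(x), " bins, median ratio ",
           signif(stats::median(y), 3), "]")
    }
  } else {
    cf <- as.list(stats::coef(fit))
  }
  structure(c(cf, list(bin_size = bin_size,
                       bins = data.frame(x = x, median_ratio = y))),
            class = "depth_correction_model")
}

#' Evaluate the depth-bias correction factor
#'
#' @param model A [fit_depth_correction()] model (or a list with the same
#'   parameter names, e.g. known true parameters).
#' @param x Distance to the nearest chromosome end, in bp.
#' @return Expected depth relative to the genomic mean at each `x`.
#' @export
depth_correction_factor <- function(model, x) {
  model$scalar * (1 - stats::plnorm(x, model$mu, model$sigma)) +
    model$intercept + model$slope * x
}

#' Correct a depth track for chromosome-end bias
#'
#' Each position's depth is divided by the model factor at its distance to
#' the nearest chromosome end.  Zero depths remain zero.
#'
#' @param track Depth track.
#' @param model Correction model (see [depth_correction_factor()]).
#' @return The corrected depth track.
#' @export
correct_depths <- function(track, model) {
  out <- lapply(names(track), function(chrom) {
    v <- track[[chrom]]
    L <- length(v)
    pos <- seq_len(L)
    f <- depth_correction_factor(model, pmin(pos, L - pos + 1L))
    if (any(f <= 0)) stop("non-positive correction factor on ", chrom)
    v / f
  })
  names(out) <- names(track)
  out
}
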