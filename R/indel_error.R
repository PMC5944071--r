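#' Aggregate observed indel error rates over repeat tracts
#'
#' Reads that fully traverse a repeat tract are informative about
#' PCR/sequencing slippage at that tract.  For one sample, traversing
#' coverage and indel-containing read counts are summed per combination of
#' event type (insertion/deletion), repeat unit length (1-4 nt) and total
#' tract length, and expressed as a rate.
#'
#' @param observations Data frame with one row per repeat tract:
#'   columns `unit` (or `unit_length`), `tract_length`,
#'   `traversing_coverage`, `insertions`, `deletions` (read counts).
#' @return A `data.frame` with columns `event` (`"insertion"`/`"deletion"`),
#'   `unit_length`, `tract_length`, `rate` and `n_loci` (distinct tracts
#'   with non-zero traversing coverage).  Strata with zero total coverage
#'   are omitted.
#' @export
aggregate_error_rates <- function(observations) {
  obs <- observations
  if (!"unit_length" %in% names(obs)) obs$unit_length <- nchar(obs$unit)
  if (any(obs$insertions > obs$traversing_coverage) ||
      any(obs$deletions > obs$traversing_coverage)) {
    stop("indel read counts cannot exceed traversing coverage")
  }
  key <- interaction(obs$unit_length, obs$tract_length, drop = TRUE)
  cov <- tapply(obs$traversing_coverage, key, sum)
  n_loci <- tapply(obs$traversing_coverage > 0, key, sum)
  ins <- tapply(obs$insertions, key, sum)
  del <- tapply(obs$deletions, key, sum)
  parts <- do.call(rbind, strsplit(names(cov), ".", fixed = TRUE))
  keep <- cov > 0
  out <- rbind(
    data.frame(event = "insertion",
               unit_length = as.integer(parts[, 1]),
               tract_length = as.integer(parts[, 2]),
               rate = as.numeric(ins / cov),
               n_loci = as.integer(n_loci), stringsAsFactors = FALSE)[keep, ],
    data.frame(event = "deletion",
               unit_length = as.integer(parts[, 1]),
               tract_length = as.integer(parts[, 2]),
               rate = as.numeric(del / cov),
               n_loci = as.integer(n_loci), stringsAsFactors = FALSE)[keep, ]
  )
  out <- out[order(out$event, out$unit_length, out$tract_length), ]
  rownames(out) <- NULL
  out
}

#' Fit the logistic indel-error-rate function
#'
#' Observed rates for one event type and unit length are fit against tract
#' length `x` with `error(x) = M + L / (1 + exp(-k (x - x0)))` by non-linear
#' least squares.  Length strata computed from fewer than `min_loci`
#' distinct repeat loci are excluded from the fit.
#'
#' @param rate_table Output of [aggregate_error_rates()].
#' @param event `"insertion"` or `"deletion"`.
#' @param unit_length Repeat unit length, 1-4.
#' @param min_loci Minimum distinct loci per length stratum (default 10).
#' @return Object of class `indel_error_fit` with `event`, `unit_length`,
#'   `M`, `L`, `k`, `x0` and `fitted_lengths`.
#' @export
fit_error_function <- function(rate_table, event, unit_length,
                               min_loci = 10L) {
  tab <- rate_table[rate_table$event == event &
                      rate_table$unit_length == unit_length &
                      rate_table$n_loci >= min_loci, , drop = FALSE]
  x <- tab$tract_length
  y <- tab$rate
  if (length(x) < 4L) stop("insufficient strata to fit indel error function")
  if (max(y) - min(y) < 1e-12) {
    # flat data: the logistic degenerates to its offset
    return(structure(list(event = event, unit_length = unit_length,
                          M = mean(y), L = 0, k = 1, x0 = stats::median(x),
                          fitted_lengths = x), class = "indel_error_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ M + L / (1 + exp(-k * (x - x0))),
      start = list(M = min(y), L = max(y) - min(y), k = 1,
                   x0 = stats::median(x)),
      lower = c(M = 0, L = 0, k = 1e-6, x0 = min(x) - 5),
      upper = c(M = Inf, L = Inf, k = 10, x0 = max(x) + 5),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) stop("indel error fit failed: ", conditionMessage(e))
  )
  cf <- stats::coef(fit)
  structure(list(event = event, unit_length = unit_length,
                 M = unname(cf["M"]), L = unname(cf["L"]),
                 k = unname(cf["k"]), x0 = unname(cf["x0"]),
                 fitted_lengths = x),
            class = "indel_error_fit")
}

#' Expected indel error rate at a tract length
#'
#' Evaluates the fitted logistic, clamped to \[0, 0.5\] so that a corrected
#' expected allele frequency can never exceed the mass of its source allele
#' under extreme extrapolation.
#'
#' @param fit An [fit_error_function()] result.
#' @param tract_length Tract length(s) in bp.
#' @return Error rate(s) in \[0, 0.5\].
#' @export
expected_error_rate <- function(fit, tract_length) {
  r <- fit$M + fit$L / (1 + exp(-fit$k * (tract_length - fit$x0)))
  pmin(pmax(r, 0), 0.5)
}

#' Build a per-sample indel error model
#'
#' Aggregates rates and fits the logistic per (event, unit length).  Where a
#' fit is impossible (too few strata) the model falls back to the stratum's
#' empirical rate, or 0 for unseen strata.
#'
#' @param observations Per-tract observations (see
#'   [aggregate_error_rates()]).
#' @param min_loci Minimum distinct loci per stratum for fitting.
#' @return Object of class `indel_error_model`.
#' @export
fit_indel_error_model <- function(observations, min_loci = 10L) {
  rates <- aggregate_error_rates(observations)
  fits <- list()
  for (event in c("insertion", "deletion")) {
    for (u in sort(unique(rates$unit_length))) {
      fit <- tryCatch(fit_error_function(rates, event, u, min_loci),
                      error = function(e) NULL)
      fits[[paste(event, u, sep = "_")]] <- fit
    }
  }
  structure(list(rates = rates, fits = fits), class = "indel_error_model")
}

#' Constant-rate indel error model
#'
#' A degenerate model returning fixed insertion and deletion rates at every
#' unit and tract length; useful for worked examples and controlled tests.
#'
#' @param insertion_rate,deletion_rate Rates in \[0, 1\].
#' @return Object of class `indel_error_model`.
#' @export
constant_indel_error_model <- function(insertion_rate, deletion_rate) {
  structure(list(constant = c(insertion = insertion_rate,
                              deletion = deletion_rate)),
            class = "indel_error_model")
}

#' Query an indel error model
#'
#' @param model An `indel_error_model`.
#' @param event `"insertion"` or `"deletion"`.
#' @param unit_length Repeat unit length.
#' @param tract_length Tract length in bp.
#' @return The expected error rate (0 when the model has no information).
#' @export
indel_error_rate <- function(model, event, unit_length, tract_length) {
  if (!is.null(model$constant)) return(unname(model$constant[event]))
  fit <- model$fits[[paste(event, unit_length, sep = "_")]]
  if (!is.null(fit)) return(expected_error_rate(fit, tract_length))
  tab <- model$rates
  hit <- tab$event == event & tab$unit_length == unit_length &
    tab$tract_length == tract_length
  if (any(hit)) return(min(max(tab$rate[hit][1], 0), 0.5))
  0
}

#' Write an indel error model's rates and fits as plain text
#'
#' @param model An `indel_error_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_indel_error_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$constant)) {
    writeLines(sprintf("# constant model: insertion=%g deletion=%g",
                       model$constant["insertion"],
                       model$constant["deletion"]), con)
    return(invisible(path))
  }
  writeLines("# fitted logistic parameters: event unit_length M L k x0", con)
  for (nm in names(model$fits)) {
    f <- model$fits[[nm]]
    if (is.null(f)) next
    writeLines(sprintf("%s\t%d\t%.6g\t%.6g\t%.6g\t%.6g",
                       f$event, f$unit_length, f$M, f$L, f$k, f$x0), con)
  }
  writeLines("# empirical rates: event unit_length tract_length rate n_loci", con)
  utils::write.table(model$rates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
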