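#' Mutation rate per base pair per generation
#'
#' `mu = N / (N_bp * gen_tot)` for `N` ploidy-accounted mutations of one
#' type observed over `N_bp` base pairs in a bin and `gen_tot` summed
#' generations.  For whole-genome rates, `N_bp` is set to the strain's
#' global ploidy.
#'
#' @param n_mutations Mutation count (ploidy-accounted), >= 0.
#' @param n_bp Base pairs in the bin (or global ploidy for whole-genome
#'   rates), > 0.
#' @param generations Total generations summed across isolates, > 0.
#' @return Rate per bp per generation.
#' @export
mutation_rate <- function(n_mutations, n_bp, generations) {
  stopifnot(n_mutations >= 0, n_bp > 0)
  if (any(generations <= 0)) stop("generations must be > 0")
  n_mutations / (n_bp * generations)
}

#' False-negative probability for indels in long repeat tracts
#'
#' Only reads that fully traverse a repeat tract are informative about an
#' indel there.  With read length `R`, tract length `L` and indel length
#' change `delta_L`, the fraction of reads crossing the whole tract is
#' `p = (R - 2 (L + delta_L)) / (R - (L + delta_L))`.  At average depth `D`
#' and an allelic-fraction cutoff `C`, the probability that too few
#' traversing reads support the indel is the binomial sum
#' `B(L; D, p) = sum_{x=0}^{L} choose(round(D C), x) p^x (1-p)^(D C - x)`.
#' Indel rates are corrected by dividing by `1 - B`.
#'
#' @param L Repeat tract length (bp).
#' @param D Average depth of coverage.
#' @param R Read length (bp).
#' @param C Allelic fraction cutoff.
#' @param delta_L Indel length change in bp (default 1).
#' @return List with `p`, `B` and `correction` (`1 / (1 - B)`).
#' @export
false_negative_rate <- function(L, D, R, C, delta_L = 1) {
  p <- (R - 2 * (L + delta_L)) / (R - (L + delta_L))
  if (!is.finite(p) || p <= 0 || p >= 1) {
    stop("traversing-read fraction p must lie in (0, 1); got ", signif(p, 4),
         " (requires R > 2 (L + delta_L))")
  }
  trials <- round(D * C)
  B <- stats::pbinom(min(L, trials), trials, p)
  list(p = p, B = B, correction = 1 / (1 - B))
}

#' Monte Carlo simulation of indel accumulation in homopolymers
#'
#' Each homopolymer tract evolves for `generations` cell divisions; per
#' generation it may gain one base (probability = insertion rate at its
#' current length), lose one base (deletion rate), or stay unchanged.
#' Rates are looked up per current length in `rates`, clamped to the
#' table's length range.  A tract whose final length is at least 2 bp below
#' its starting length counts as a multi-base deletion, so the simulation
#' quantifies how often sequential single-base events alone would produce
#' multi-base deletions.
#'
#' @param rates Data frame with columns `length`, `insertion_rate`,
#'   `deletion_rate` (typically lengths 7-18).
#' @param census Named integer vector: number of genomic tracts per
#'   starting length (names are lengths).
#' @param generations Number of generations.
#' @param iterations Monte Carlo iterations (default 5000).
#' @param seed Integer seed.
#' @return A `data.frame` per starting length: `length`, `n_tracts`,
#'   `mean_multibase_deletions` (mean count per iteration across the
#'   tracts of that length), `q025`, `q975` (central 95% envelope) and
#'   `fraction` (per-tract multi-base deletion probability).
#' @export
simulate_indel_accumulation <- function(rates, census, generations,
                                        iterations = 5000L, seed = 1L) {
  stopifnot(iterations >= 1, all(rates$insertion_rate >= 0),
            all(rates$deletion_rate >= 0),
            all(rates$insertion_rate + rates$deletion_rate <= 1))
  lens <- as.integer(names(census))
  lmin <- min(rates$length); lmax <- max(rates$length)
  ins <- stats::setNames(rates$insertion_rate, rates$length)
  del <- stats::setNames(rates$deletion_rate, rates$length)
  lookup <- function(l) as.character(pmin(pmax(l, lmin), lmax))
  with_seed(seed, {
    out <- lapply(seq_along(lens), function(j) {
      n <- census[[j]]
      if (n == 0L) return(NULL)
      cur <- matrix(lens[j], nrow = iterations, ncol = n)
      for (g in seq_len(generations)) {
        key <- lookup(cur)
        rd <- del[key]; ri <- ins[key]
        u <- stats::runif(length(cur))
        cur <- cur - (u < rd) + (u >= rd & u < rd + ri)
      }
      multi <- matrix(cur <= lens[j] - 2L, nrow = iterations)
      per_iter <- rowSums(multi)
      data.frame(length = lens[j], n_tracts = n,
                 mean_multibase_deletions = mean(per_iter),
                 q025 = unname(stats::quantile(per_iter, 0.025)),
                 q975 = unname(stats::quantile(per_iter, 0.975)),
                 fraction = mean(multi))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
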