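#' Enumerate candidate genotype models at a site
#'
#' A model is either a clonal genotype alone (a multiset of observed alleles
#' with cardinality equal to the local copy number), or a clonal genotype
#' plus a subclonal genotype differing in exactly one allele, carried at a
#' fixed fraction.  Allowed subclonal fractions are 0.500, 0.250 and 0.125,
#' corresponding to a mutation in the first, second or third division after
#' the final bottleneck.
#'
#' @param alleles Character vector of alleles observed at the site.
#' @param copy_number Local copy number (>= 1).
#' @param fractions Allowed subclonal fractions.
#' @return A list of models; each model is a list with `clonal` (sorted
#'   allele vector), and for subclonal models `sub_from`, `sub_to`,
#'   `fraction` (otherwise `NULL`/`NA`).  Clonal-only models come first;
#'   the order is deterministic.
#' @export
enumerate_genotype_models <- function(alleles, copy_number,
                                      fractions = c(0.5, 0.25, 0.125)) {
  stopifnot(length(alleles) >= 1, copy_number >= 1)
  alleles <- sort(unique(alleles))
  n <- length(alleles)
  # multisets of size copy_number over n alleles
  combs <- utils::combn(n + copy_number - 1L, copy_number)
  clonals <- lapply(seq_len(ncol(combs)), function(j) {
    sort(alleles[combs[, j] - seq_len(copy_number) + 1L])
  })
  models <- lapply(clonals, function(g) {
    list(clonal = g, sub_from = NA_character_, sub_to = NA_character_,
         fraction = NA_real_)
  })
  seen <- vapply(clonals, multiset_key, character(1))
  seen_sub <- character(0)
  for (g in clonals) {
    for (f_allele in unique(g)) {
      for (b in setdiff(alleles, f_allele)) {
        sub <- sort(c(multiset_diff(g, f_allele), b))
        for (frac in fractions) {
          key <- paste(multiset_key(g), multiset_key(sub), frac, sep = "\n")
          if (key %in% seen_sub) next
          seen_sub <- c(seen_sub, key)
          models[[length(models) + 1L]] <-
            list(clonal = g, sub_from = f_allele, sub_to = b, fraction = frac)
        }
      }
    }
  }
  models
}

#' Expected allelic frequencies under a genotype model
#'
#' For a clonal genotype, an optional subclonal genotype (the clonal with
#' one allele substituted) and a subclonal fraction `f`, the expected
#' frequency of each allele is
#' `(1 - f) * count_clonal / |clonal| + f * count_subclonal / |subclonal|`.
#'
#' @param model A model from [enumerate_genotype_models()].
#' @param alleles Site alleles over which to report frequencies.
#' @return Named numeric vector of frequencies (non-negative, summing to 1).
#' @export
expected_frequencies <- function(model, alleles = NULL) {
  g <- model$clonal
  sub <- if (!is.null(model$fraction) && !is.na(model$fraction)) {
    sort(c(multiset_diff(g, model$sub_from), model$sub_to))
  } else NULL
  all_alleles <- sort(unique(c(alleles, g, sub)))
  freq <- stats::setNames(numeric(length(all_alleles)), all_alleles)
  tab <- table(g)
  if (is.null(sub)) {
    freq[names(tab)] <- as.numeric(tab) / length(g)
  } else {
    f <- model$fraction
    freq[names(tab)] <- (1 - f) * as.numeric(tab) / length(g)
    stab <- table(sub)
    freq[names(stab)] <- freq[names(stab)] + f * as.numeric(stab) / length(sub)
  }
  freq
}

#' Repeat context of a variant site
#'
#' Locates the repeat tract enclosing a position and checks that the site's
#' allele length differences are whole multiples of the tract's unit length
#' (so that single-unit slippage alleles are well defined).  When several
#' tracts qualify the longest is used.
#'
#' @param repeats Repeat table from [find_repeats()].
#' @param chrom,pos Site coordinates (1-based).
#' @param alleles Site alleles, reference first.
#' @return `NULL` when the site has no usable repeat context, else a list
#'   with `unit`, `unit_length`, `ref_allele` and `ref_tract_length`.
#' @export
repeat_context <- function(repeats, chrom, pos, alleles) {
  if (is.null(repeats) || nrow(repeats) == 0L) return(NULL)
  hit <- repeats[repeats$chrom == chrom & repeats$start <= pos &
                   repeats$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  ref <- alleles[1]
  diffs <- nchar(alleles) - nchar(ref)
  ok <- vapply(seq_len(nrow(hit)), function(i) {
    u <- nchar(hit$unit[i])
    all(diffs %% u == 0)
  }, logical(1))
  hit <- hit[ok, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  i <- which.max(hit$tract_length)
  list(unit = hit$unit[i], unit_length = nchar(hit$unit[i]),
       ref_allele = ref, ref_tract_length = hit$tract_length[i])
}

#' Apply single-unit indel error correction to expected frequencies
#'
#' At repeat-context sites, PCR slippage moves part of each allele's
#' expected mass to its single-unit neighbours: for a genotype allele with
#' mass `m`, `m * rate_del` is moved to the allele one repeat unit shorter
#' and `m * rate_ins` to the allele one unit longer (creating alleles as
#' needed).  Total mass is conserved.  Without a repeat context the
#' frequencies are returned unchanged.
#'
#' @param freqs Named expected-frequency vector.
#' @param context A [repeat_context()] (or `NULL`).
#' @param error_model An `indel_error_model` (or `NULL`).
#' @return Corrected named frequency vector.
#' @export
correct_for_indel_error <- function(freqs, context, error_model) {
  if (is.null(context) || is.null(error_model)) return(freqs)
  u <- context$unit_length
  base_len <- context$ref_tract_length - nchar(context$ref_allele)
  source_alleles <- names(freqs)[freqs > 0]
  out <- freqs
  for (a in source_alleles) {
    m <- freqs[[a]]
    tlen <- base_len + nchar(a)
    r_del <- indel_error_rate(error_model, "deletion", u, tlen)
    r_ins <- indel_error_rate(error_model, "insertion", u, tlen)
    if (r_del > 0 && nchar(a) > u) {
      target <- substr(a, 1L, nchar(a) - u)
      out[a] <- out[a] - m * r_del
      out[target] <- (if (target %in% names(out)) out[[target]] else 0) +
        m * r_del
    }
    if (r_ins > 0) {
      target <- paste0(a, context$unit)
      out[a] <- out[a] - m * r_ins
      out[target] <- (if (target %in% names(out)) out[[target]] else 0) +
        m * r_ins
    }
  }
  out[sort(names(out))]
}

#' Floor zero expected frequencies
#'
#' Zero frequencies are replaced by `2 / total_depth`, one pseudo-count per
#' strand, preventing division by zero in the genotype score.  Non-zero
#' frequencies are untouched and no renormalisation is applied.
#'
#' @param freqs Named frequency vector.
#' @param total_depth Total read depth at the site for this sample (> 0).
#' @return Floored frequency vector.
#' @export
floor_frequencies <- function(freqs, total_depth) {
  if (total_depth <= 0) stop("total_depth must be > 0")
  freqs[freqs == 0] <- 2 / total_depth
  freqs
}

#' Score a genotype model against observed frequencies
#'
#' `score = sum_i | ln(o_i / e_i) |` over alleles; zero iff observed equals
#' expected on every allele.  Inputs must be positive (flooring applied
#' beforehand) and cover the same allele set.
#'
#' @param observed,expected Named positive frequency vectors over the same
#'   alleles.
#' @return Non-negative score.
#' @export
score_genotype <- function(observed, expected) {
  alleles <- names(expected)
  stopifnot(all(alleles %in% names(observed)))
  sum(abs(log(observed[alleles] / expected[alleles])))
}

#' Call the genotype at one site for one sample
#'
#' Enumerates all clonal and clonal+subclonal models, computes expected
#' allelic frequencies with single-unit indel error correction and
#' pseudo-count flooring, and selects the model with the minimum score.
#' Score ties are broken by the most reference-allele copies (t0 samples)
#' or the most alleles shared with the t0 clonal genotype (outgrowths);
#' remaining ties fall to the first model in the deterministic enumeration
#' order (clonal-only models first).
#'
#' @param counts 2 x n_alleles strand count matrix for the sample.
#' @param alleles Site alleles, reference first.
#' @param copy_number Local copy number.
#' @param context Repeat context ([repeat_context()] or `NULL`).
#' @param error_model Per-sample `indel_error_model` (or `NULL`).
#' @param role `"t0"` or `"outgrowth"`.
#' @param t0_call The t0 [call_genotype()] result (required for
#'   outgrowths).
#' @return `NULL` if the sample has no reads at the site; otherwise a list
#'   of class `genotype_call` with `clonal`, `sub_from`, `sub_to`,
#'   `fraction`, `score` and `depth`.
#' @export
call_genotype <- function(counts, alleles, copy_number, context = NULL,
                          error_model = NULL, role = c("t0", "outgrowth"),
                          t0_call = NULL) {
  role <- match.arg(role)
  if (role == "outgrowth" && is.null(t0_call)) {
    stop("t0_call is required to call an outgrowth genotype")
  }
  total <- sum(counts)
  if (total == 0) return(NULL)
  pooled <- colSums(counts)
  models <- enumerate_genotype_models(alleles, copy_number)
  scores <- numeric(length(models))
  for (i in seq_along(models)) {
    e <- expected_frequencies(models[[i]], alleles)
    e <- correct_for_indel_error(e, context, error_model)
    # error mass moved to alleles the caller never reported depletes its
    # source but is not scored: an allele with no observed reads carries no
    # evidence, and its floored observed/expected ratio would be artifact
    e <- e[names(e) %in% alleles]
    e <- floor_frequencies(e, total)
    o <- stats::setNames(numeric(length(e)), names(e))
    o[names(pooled)] <- pooled / total
    o <- floor_frequencies(o, total)
    scores[i] <- score_genotype(o, e)
  }
  best <- min(scores)
  tied <- which(scores <= best + 1e-9)
  if (length(tied) > 1L) {
    pref <- if (role == "t0") {
      vapply(tied, function(i) sum(models[[i]]$clonal == alleles[1]),
             numeric(1))
    } else {
      vapply(tied, function(i) {
        length(multiset_intersect(models[[i]]$clonal, t0_call$clonal))
      }, numeric(1))
    }
    tied <- tied[pref == max(pref)]
  }
  sel <- models[[tied[1]]]
  structure(list(clonal = sel$clonal, sub_from = sel$sub_from,
                 sub_to = sel$sub_to, fraction = sel$fraction,
                 score = scores[tied[1]], depth = total,
                 reverted = NA_character_),
            class = "genotype_call")
}

#' Validate a subclonal genotype call
#'
#' A called subclonal component must survive two tests.  (1) A binomial
#' test: the pooled read count of the differentiating subclonal allele is
#' compared against the rate expected under the clonal-only genotype (its
#' floored, error-corrected expected frequency); the upper-tail p-value
#' must fall below the Sidak per-test threshold
#' `1 - (1 - fwer)^(1/n_tests)`.  (2) A strand-bias test: the two-tailed
#' strand-bias p-value of the subclonal allele's reads must not fall below
#' the same threshold.  Failing either test reverts the call to the clonal
#' genotype; a strand-bias failure in a t0 sample additionally flags the
#' site so that no mutations are reported there.
#'
#' @param call A [call_genotype()] result with a subclonal component.
#' @param counts The sample's 2 x n_alleles strand count matrix.
#' @param alleles Site alleles, reference first.
#' @param context,error_model As in [call_genotype()].
#' @param bias_distribution A [fit_strand_bias_distribution()] result.
#' @param n_tests Number of queryable genome positions (Sidak test count).
#' @param fwer Family-wise error rate (default 0.01).
#' @return The call, possibly with the subclonal component removed
#'   (`reverted` records the reason) and, for t0 strand-bias failures,
#'   `suppress_site = TRUE`.
#' @param role `"t0"` or `"outgrowth"`.
#' @export
validate_subclonal <- function(call, counts, alleles, context = NULL,
                               error_model = NULL, bias_distribution,
                               n_tests, fwer = 0.01,
                               role = c("t0", "outgrowth")) {
  role <- match.arg(role)
  if (is.na(call$fraction)) return(call)
  alpha <- sidak_alpha(fwer, n_tests)
  allele <- call$sub_to
  total <- sum(counts)
  k <- if (allele %in% colnames(counts)) sum(counts[, allele]) else 0
  clonal_model <- list(clonal = call$clonal, fraction = NA_real_)
  e <- expected_frequencies(clonal_model, alleles)
  e <- correct_for_indel_error(e, context, error_model)
  e <- e[names(e) %in% alleles]
  e <- floor_frequencies(e, total)
  rate <- if (allele %in% names(e)) e[[allele]] else 2 / total
  p_binom <- stats::pbinom(k - 1, total, rate, lower.tail = FALSE)
  revert <- function(reason) {
    call$sub_from <- NA_character_
    call$sub_to <- NA_character_
    call$fraction <- NA_real_
    call$reverted <- reason
    call
  }
  if (p_binom > alpha) return(revert("binomial"))
  top <- if (allele %in% colnames(counts)) counts["top", allele] else 0
  bottom <- if (allele %in% colnames(counts)) counts["bottom", allele] else 0
  p_bias <- strand_bias_p_value(top, bottom, bias_distribution)
  if (p_bias < alpha) {
    call <- revert("strand_bias")
    if (role == "t0") call$suppress_site <- TRUE
    return(call)
  }
  call
}
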