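#' Sidak per-test significance threshold
#'
#' Controls the family-wise error rate over `n_tests` independent tests:
#' `alpha = 1 - (1 - fwer)^(1/n_tests)`.  The number of tests is taken as
#' the number of queryable genome positions.
#'
#' @param fwer Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return Per-test alpha in (0, fwer].
#' @export
sidak_alpha <- function(fwer, n_tests) {
  stopifnot(fwer > 0, fwer < 1, n_tests >= 1)
  -expm1(log1p(-fwer) / n_tests)
}

# A site is skipped when either sample's reads all map to a single strand,
# or when only one allele has coverage across both samples.
site_degenerate <- function(t0_counts, outgrowth_counts) {
  single_strand <- function(m) sum(rowSums(m) > 0) < 2L
  if (single_strand(t0_counts) || single_strand(outgrowth_counts)) return(TRUE)
  observed <- colSums(t0_counts) + colSums(outgrowth_counts)
  sum(observed > 0) < 2L
}

#' Compare outgrowth read counts against t0 at one site
#'
#' Three statistics are computed.  (1) A chi-square goodness-of-fit test
#' over all allele-by-strand cells: expected outgrowth cell counts are the
#' t0 cell proportions (with one pseudo-count per cell) times the outgrowth
#' total, with `cells - 1` degrees of freedom.  (2, 3) Per allele and per
#' strand, an upper-tail binomial p-value of the outgrowth allele count
#' given the t0 allele fraction on the same strand (pseudo-counted where the
#' t0 count is 0).  A composite score per allele is the Euclidean norm of
#' the three -log10 p-values — the distance from certainty that no mutation
#' occurred.
#'
#' @param t0_counts,outgrowth_counts 2 x n_alleles strand count matrices
#'   (rows `top`, `bottom`).
#' @return List with `p_chi` and a per-allele `data.frame` (`allele`,
#'   `p_top`, `p_bottom`, `composite`), or `NULL` when the site is
#'   degenerate (single-strand sample or single observed allele).
#' @export
compare_site <- function(t0_counts, outgrowth_counts) {
  if (site_degenerate(t0_counts, outgrowth_counts)) return(NULL)
  n_alleles <- ncol(t0_counts)
  cells_t0 <- as.numeric(t0_counts) + 1
  props <- cells_t0 / sum(cells_t0)
  obs <- as.numeric(outgrowth_counts)
  expected <- props * sum(obs)
  stat <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  p_chi <- stats::pchisq(stat, df, lower.tail = FALSE)

  alleles <- colnames(t0_counts)
  p_strand <- function(strand) {
    n_t0 <- sum(t0_counts[strand, ])
    n_out <- sum(outgrowth_counts[strand, ])
    vapply(seq_len(n_alleles), function(a) {
      p0 <- if (t0_counts[strand, a] == 0) {
        1 / (n_t0 + 1)
      } else {
        t0_counts[strand, a] / n_t0
      }
      stats::pbinom(outgrowth_counts[strand, a] - 1, n_out, p0,
                    lower.tail = FALSE)
    }, numeric(1))
  }
  p_top <- p_strand("top")
  p_bottom <- p_strand("bottom")
  composite <- sqrt(log10(p_top)^2 + log10(p_bottom)^2 + log10(p_chi)^2)
  list(p_chi = p_chi,
       alleles = data.frame(allele = alleles, p_top = p_top,
                            p_bottom = p_bottom, composite = composite,
                            stringsAsFactors = FALSE))
}

#' Mutation decision thresholds
#'
#' @param fwer Family-wise error rate (default 0.01).
#' @param n_tests Number of queryable genome positions.
#' @param marginal_p_max Per-test marginal p-value ceiling (default 0.1).
#' @param min_depth Minimum read depth in both samples (default 20).
#' @return List of thresholds including the Sidak `per_test_alpha` and the
#'   composite-score threshold `-log10(per_test_alpha)`.
#' @export
mutation_thresholds <- function(fwer = 0.01, n_tests, marginal_p_max = 0.1,
                                min_depth = 20L) {
  alpha <- sidak_alpha(fwer, n_tests)
  list(fwer = fwer, n_tests = n_tests, per_test_alpha = alpha,
       composite_threshold = -log10(alpha), marginal_p_max = marginal_p_max,
       min_depth = min_depth)
}

#' Decide whether a site carries a putative mutation
#'
#' The site is putative when `p_chi < marginal_p_max` and at least one
#' allele has a composite score above the FWER-derived threshold with both
#' per-strand binomial p-values below `marginal_p_max`.
#'
#' @param stats A [compare_site()] result.
#' @param thresholds A [mutation_thresholds()] list.
#' @return List with `call` (logical) and `alleles` (character vector of
#'   alleles meeting the per-allele conditions).
#' @export
decide_mutation <- function(stats, thresholds) {
  if (is.null(stats)) return(list(call = FALSE, alleles = character(0)))
  a <- stats$alleles
  hit <- a$composite > thresholds$composite_threshold &
    a$p_top < thresholds$marginal_p_max &
    a$p_bottom < thresholds$marginal_p_max
  call <- stats$p_chi < thresholds$marginal_p_max && any(hit)
  list(call = call, alleles = a$allele[hit])
}

in_regions <- function(regions, chrom, pos) {
  if (is.null(regions) || nrow(regions) == 0L) return(FALSE)
  any(regions$chrom == chrom & regions$start < pos & regions$end >= pos)
}

#' Call mutations for one outgrowth sample against t0
#'
#' Runs the per-site statistical comparison, decision rule, genotype
#' calling, subclonal validation and parsimonious event inference over a
#' list of candidate sites, applying the site filters in order: user
#' exclusion regions; abnormal-depth regions (either sample); minimum depth
#' (either sample); degenerate single-strand/single-allele coverage;
#' statistical thresholds; t0 subclonal strand bias.  Sites whose t0 and
#' outgrowth genotypes do not differ yield no mutation record.
#'
#' @param sites List of site objects (see [read_counts_table()]).
#' @param t0,outgrowth Sample names.
#' @param ploidy Named list/vector of sample ploidies.
#' @param n_tests Number of queryable genome positions.
#' @param error_models Named list of per-sample `indel_error_model`s
#'   (optional).
#' @param bias_distributions Named list of per-sample strand-bias
#'   distributions (optional; without them subclonal validation applies
#'   only the binomial test).
#' @param repeats Repeat table for error-correction context (optional).
#' @param abnormal_regions Named list of per-sample BED-style region data
#'   frames from [detect_abnormal_regions()] (optional).
#' @param exclusions BED-style exclusion data frame (optional).
#' @param copy_number_maps Named list of per-sample copy-number maps
#'   (optional).
#' @param fwer Family-wise error rate (default 0.01).
#' @param min_depth Depth filter (default 20).
#' @return List with `records` (a `data.frame` of reported mutations, one
#'   row per mutation site) and `site_status` (per-site filter status).
#' @export
call_mutations <- function(sites, t0, outgrowth, ploidy, n_tests,
                           error_models = NULL, bias_distributions = NULL,
                           repeats = NULL, abnormal_regions = NULL,
                           exclusions = NULL, copy_number_maps = NULL,
                           fwer = 0.01, min_depth = 20L) {
  thresholds <- mutation_thresholds(fwer, n_tests, min_depth = min_depth)
  status <- character(length(sites))
  records <- list()
  for (i in seq_along(sites)) {
    site <- sites[[i]]
    m_t0 <- site$counts[[t0]]
    m_out <- site$counts[[outgrowth]]
    if (is.null(m_t0) || is.null(m_out)) stop("sample missing from site counts")
    if (in_regions(exclusions, site$chrom, site$pos)) {
      status[i] <- "excluded_region"; next
    }
    if (in_regions(abnormal_regions[[t0]], site$chrom, site$pos) ||
        in_regions(abnormal_regions[[outgrowth]], site$chrom, site$pos)) {
      status[i] <- "abnormal_depth"; next
    }
    if (sum(m_t0) < min_depth || sum(m_out) < min_depth) {
      status[i] <- "low_depth"; next
    }
    if (site_degenerate(m_t0, m_out)) {
      status[i] <- "single_strand_single_allele"; next
    }
    stats <- compare_site(m_t0, m_out)
    decision <- decide_mutation(stats, thresholds)
    if (!decision$call) {
      status[i] <- "below_threshold"; next
    }
    context <- repeat_context(repeats, site$chrom, site$pos, site$alleles)
    cn <- function(sample) {
      local_copy_number(copy_number_maps[[sample]], site$chrom, site$pos,
                        ploidy[[sample]])
    }
    t0_call <- call_genotype(m_t0, site$alleles, cn(t0), context,
                             error_models[[t0]], role = "t0")
    out_call <- call_genotype(m_out, site$alleles, cn(outgrowth), context,
                              error_models[[outgrowth]], role = "outgrowth",
                              t0_call = t0_call)
    if (is.null(t0_call) || is.null(out_call)) {
      status[i] <- "low_depth"; next
    }
    suppress <- FALSE
    if (!is.na(t0_call$fraction) && !is.null(bias_distributions[[t0]])) {
      t0_call <- validate_subclonal(t0_call, m_t0, site$alleles, context,
                                    error_models[[t0]],
                                    bias_distributions[[t0]], n_tests, fwer,
                                    role = "t0")
      suppress <- isTRUE(t0_call$suppress_site)
    }
    if (suppress) {
      status[i] <- "t0_subclonal_bias"; next
    }
    if (!is.na(out_call$fraction) && !is.null(bias_distributions[[outgrowth]])) {
      out_call <- validate_subclonal(out_call, m_out, site$alleles, context,
                                     error_models[[outgrowth]],
                                     bias_distributions[[outgrowth]],
                                     n_tests, fwer, role = "outgrowth")
    }
    inferred <- infer_mutation_events(t0_call, out_call, site$alleles,
                                      site$chrom, site$pos)
    if (length(inferred$events) == 0L && is.na(out_call$fraction)) {
      status[i] <- "no_genotype_change"; next
    }
    status[i] <- "pass"
    records[[length(records) + 1L]] <- data.frame(
      chrom = site$chrom, pos = site$pos, sample = outgrowth,
      ref = site$alleles[1],
      alt = paste(setdiff(decision$alleles, site$alleles[1]), collapse = ","),
      t0_genotype = paste(t0_call$clonal, collapse = "|"),
      outgrowth_genotype = paste(out_call$clonal, collapse = "|"),
      subclonal_allele = out_call$sub_to,
      subclonal_fraction = out_call$fraction,
      hgvs = inferred$hgvs, pac = inferred$pac,
      p_chi = stats$p_chi,
      max_composite = max(stats$alleles$composite),
      filter_status = "pass",
      stringsAsFactors = FALSE)
  }
  records <- if (length(records)) do.call(rbind, records) else empty_records()
  rownames(records) <- NULL
  site_status <- data.frame(
    chrom = vapply(sites, `[[`, character(1), "chrom"),
    pos = vapply(sites, `[[`, integer(1), "pos"),
    filter_status = status, stringsAsFactors = FALSE)
  list(records = records, site_status = site_status,
       thresholds = thresholds)
}

local_copy_number <- function(map, chrom, pos, ploidy) {
  if (is.null(map)) return(as.integer(ploidy))
  hit <- map$chrom == chrom & map$start < pos & map$end >= pos
  if (any(hit)) as.integer(map$copy_number[which(hit)[1]]) else as.integer(ploidy)
}

empty_records <- function() {
  data.frame(chrom = character(0), pos = integer(0), sample = character(0),
             ref = character(0), alt = character(0),
             t0_genotype = character(0), outgrowth_genotype = character(0),
             subclonal_allele = character(0), subclonal_fraction = numeric(0),
             hgvs = character(0), pac = character(0), p_chi = numeric(0),
             max_composite = numeric(0), filter_status = character(0),
             stringsAsFactors = FALSE)
}
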