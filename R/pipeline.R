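#' Assemble a pipeline configuration
#'
#' @param sample_sheet Path to the sample sheet (or a validated data
#'   frame).
#' @param reference Path to the reference FASTA (or a named character
#'   vector of sequences).
#' @param output_dir Output directory.
#' @param repeat_file Optional pre-computed repeat table path; when `NULL`
#'   repeats are found from the reference.
#' @param exclusions Optional BED path of user-excluded regions.
#' @param copy_number Optional BED-like copy-number map path (4th column =
#'   copy number).
#' @param fwer Family-wise error rate (default 0.01).
#' @param depth_p_threshold Abnormal-depth p-value threshold (default 1e-4).
#' @param merge_distance Abnormal-region merge distance (default 1000).
#' @param window Depth moving-average window (default 25).
#' @param min_depth Minimum depth filter (default 20).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_sheet, reference, output_dir,
                            repeat_file = NULL, exclusions = NULL,
                            copy_number = NULL, fwer = 0.01,
                            depth_p_threshold = 1e-4,
                            merge_distance = 1000L, window = 25L,
                            min_depth = 20L) {
  structure(list(sample_sheet = sample_sheet, reference = reference,
                 output_dir = output_dir, repeat_file = repeat_file,
                 exclusions = exclusions, copy_number = copy_number,
                 fwer = fwer, depth_p_threshold = depth_p_threshold,
                 merge_distance = merge_distance, window = window,
                 min_depth = min_depth),
            class = "pipeline_config")
}

read_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    dna <- Biostrings::readDNAStringSet(reference)
    seqs <- as.character(dna)
    names(seqs) <- sub("\\s.*$", "", names(dna))
    return(seqs)
  }
  if (is.list(reference) && !is.null(reference$seq)) return(reference$seq)
  reference
}

#' Run the full mutation-calling pipeline
#'
#' Per sample: read the depth track, fit the depth distribution, detect
#' abnormal-depth regions, fit the strand-bias distribution from the counts
#' table, and fit the indel error model from repeat observations (when a
#' `repeat_obs_path` column is present).  Then, per outgrowth: compare
#' counts to t0 site by site, apply the decision rule and filters, call
#' genotypes at putative sites, infer mutation events and write the TSV and
#' VCF reports, per-sample region BEDs, depth bedGraphs and plain-text
#' model parameter files.  The Sidak test count is the genome length minus
#' positions excluded or flagged as abnormal for the outgrowth under
#' consideration.
#'
#' @param config A [pipeline_config()].
#' @param models Optional pre-computed models (as returned in the result's
#'   `models` element) to re-call mutations under revised assumptions
#'   without re-fitting.
#' @return List with `records` (all outgrowths), `site_status`, `models`,
#'   and `output_dir`; invisibly writes the report files.
#' @export
run_pipeline <- function(config, models = NULL) {
  sheet <- if (is.data.frame(config$sample_sheet)) {
    validate_sample_sheet(config$sample_sheet)
  } else {
    read_sample_sheet(config$sample_sheet)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("pipeline started; fwer=%g min_depth=%d window=%d p_threshold=%g merge=%d",
       config$fwer, config$min_depth, config$window,
       config$depth_p_threshold, config$merge_distance)

  reference <- read_reference(config$reference)
  chrom_lengths <- stats::setNames(nchar(reference), names(reference))
  genome_length <- sum(chrom_lengths)
  repeats <- if (!is.null(config$repeat_file)) {
    read_repeat_file(config$repeat_file)
  } else {
    find_repeats(reference)
  }
  exclusions <- if (!is.null(config$exclusions)) read_bed(config$exclusions)
  cn_map <- if (!is.null(config$copy_number)) {
    read_copy_number_map(config$copy_number)
  }

  t0 <- sheet$name[sheet$role == "t0"]
  counts_path <- sheet$counts_path[1]
  sites <- read_counts_table(counts_path, sheet$name)
  logf("loaded %d candidate sites for samples: %s", length(sites),
       paste(sheet$name, collapse = ", "))

  if (is.null(models)) {
    models <- list(depth = list(), regions = list(), bias = list(),
                   indel = list())
    for (i in seq_len(nrow(sheet))) {
      s <- sheet$name[i]
      track <- read_bedgraph(sheet$depth_path[i], chrom_lengths)
      dist <- fit_depth_distribution(track, sheet$ploidy[i], cn_map)
      regions <- detect_abnormal_regions(track, dist, sheet$ploidy[i], cn_map,
                                         window = config$window,
                                         p_threshold = config$depth_p_threshold,
                                         merge_distance = config$merge_distance)
      top <- vapply(sites, function(x) sum(x$counts[[s]]["top", ]), numeric(1))
      bottom <- vapply(sites, function(x) sum(x$counts[[s]]["bottom", ]),
                       numeric(1))
      bias <- tryCatch(fit_strand_bias_distribution(top, bottom),
                       error = function(e) NULL)
      indel <- NULL
      if ("repeat_obs_path" %in% names(sheet) &&
          !is.na(sheet$repeat_obs_path[i]) &&
          nzchar(sheet$repeat_obs_path[i])) {
        obs <- utils::read.delim(sheet$repeat_obs_path[i],
                                 stringsAsFactors = FALSE)
        indel <- fit_indel_error_model(obs)
      }
      models$depth[[s]] <- dist
      models$regions[[s]] <- regions
      models$bias[[s]] <- bias
      models$indel[[s]] <- indel
      write_bed(regions, file.path(config$output_dir,
                                   paste0(s, "_abnormal_regions.bed")))
      writeLines(sprintf("depth per-copy mean\t%.6g\ndepth per-copy sd\t%.6g\nstrand bias mean\t%.6g\nstrand bias sd\t%.6g",
                         dist$mean, dist$sd,
                         if (is.null(bias)) NA else bias$mean,
                         if (is.null(bias)) NA else bias$sd),
                 file.path(config$output_dir, paste0(s, "_distributions.txt")))
      if (!is.null(indel)) {
        write_indel_error_model(indel, file.path(config$output_dir,
                                                 paste0(s, "_indel_error.txt")))
      }
      logf("sample %s: depth %.2f +/- %.2f per copy; %d abnormal regions",
           s, dist$mean, dist$sd, nrow(regions))
    }
  } else {
    logf("re-using supplied models (recall)")
  }

  ploidy <- stats::setNames(as.list(sheet$ploidy), sheet$name)
  cn_maps <- if (!is.null(cn_map)) {
    stats::setNames(rep(list(cn_map), nrow(sheet)), sheet$name)
  }
  all_records <- list()
  all_status <- list()
  for (s in sheet$name[sheet$role == "outgrowth"]) {
    masked <- 0
    for (regs in list(models$regions[[t0]], models$regions[[s]], exclusions)) {
      if (!is.null(regs) && nrow(regs) > 0) {
        masked <- masked + sum(regs$end - regs$start)
      }
    }
    n_tests <- max(genome_length - masked, 1)
    res <- call_mutations(sites, t0, s, ploidy, n_tests,
                          error_models = models$indel,
                          bias_distributions = models$bias,
                          repeats = repeats,
                          abnormal_regions = models$regions,
                          exclusions = exclusions,
                          copy_number_maps = cn_maps,
                          fwer = config$fwer, min_depth = config$min_depth)
    all_records[[s]] <- res$records
    status <- res$site_status
    status$sample <- s
    all_status[[s]] <- status
    logf("outgrowth %s: %d/%d sites pass (n_tests=%d)", s,
         nrow(res$records), length(sites), as.integer(n_tests))
  }
  records <- do.call(rbind, c(all_records, list(empty_records())))
  rownames(records) <- NULL
  write_mutations_tsv(records, file.path(config$output_dir, "mutations.tsv"))
  write_mutations_vcf(records, reference,
                      file.path(config$output_dir, "mutations.vcf"))
  logf("wrote %d mutation records", nrow(records))
  invisible(list(records = records,
                 site_status = do.call(rbind, all_status),
                 models = models, output_dir = config$output_dir))
}

#' Re-call mutations under updated models or assumptions
#'
#' Skips model fitting and re-runs only the mutation-calling stage, e.g.
#' after depth correction or under a revised whole-genome ploidy.
#'
#' @param config A [pipeline_config()] (fields may be revised, e.g. the
#'   sample sheet's ploidy column).
#' @param models Models from a previous [run_pipeline()] result.
#' @return As [run_pipeline()].
#' @export
recall_mutations <- function(config, models) {
  if (is.null(models)) stop("recall requires models from a previous run")
  run_pipeline(config, models = models)
}

# -- report writers -----------------------------------------------------------

#' Write mutation records as a tab-delimited report
#'
#' @param records Mutation record data frame from [call_mutations()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mutations_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write mutation records as VCF 4.2
#'
#' One record per mutation position per sample.  `FILTER` carries the
#' filter status, `INFO` carries the sample, PAC flag, HGVS string and
#' genotypes.  The reference base at each position is checked against the
#' reference sequence.
#'
#' @param records Mutation record data frame.
#' @param reference Named character vector of chromosome sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mutations_vcf <- function(records, reference, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=macall",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Outgrowth sample\">",
    "##INFO=<ID=PAC,Number=1,Type=String,Description=\"Potential allelic conversion flag\">",
    "##INFO=<ID=HGVS,Number=1,Type=String,Description=\"HGVS-style event names; ambiguous alternatives pipe-separated\">",
    "##INFO=<ID=AMBIG,Number=0,Type=Flag,Description=\"Event identity is ambiguous\">",
    "##FILTER=<ID=excluded_region,Description=\"In user exclusion BED\">",
    "##FILTER=<ID=abnormal_depth,Description=\"In abnormal-depth region\">",
    "##FILTER=<ID=low_depth,Description=\"Depth below threshold\">",
    "##FILTER=<ID=t0_subclonal_bias,Description=\"Strand bias in t0 subclonal allele\">",
    "##FILTER=<ID=single_strand_single_allele,Description=\"Degenerate coverage pattern\">",
    "##FILTER=<ID=below_threshold,Description=\"Statistical thresholds not met\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(records) > 0) {
    reference <- read_reference(reference)
    body <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      ref_seq <- substr(reference[[r$chrom]], r$pos,
                        r$pos + nchar(r$ref) - 1L)
      if (!is.null(reference[[r$chrom]]) &&
          toupper(ref_seq) != toupper(r$ref)) {
        stop("reference mismatch at ", r$chrom, ":", r$pos, " (", ref_seq,
             " != ", r$ref, ")")
      }
      alt <- if (is.na(r$alt) || !nzchar(r$alt)) "." else r$alt
      info <- paste0("SAMPLE=", r$sample, ";PAC=", r$pac, ";HGVS=", r$hgvs)
      if (grepl("|", r$hgvs, fixed = TRUE)) info <- paste0(info, ";AMBIG")
      paste(r$chrom, r$pos, ".", r$ref, alt, ".",
            if (r$filter_status == "pass") "PASS" else r$filter_status,
            info, sep = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
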