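# Seeded synthetic data with known ground truth: reference sequences with
# planted repeat tracts, per-sample depth tracks, strand-specific counts
# tables for an ancestor/descendant pair, and per-tract traversing-coverage
# observations for the indel error model.

#' Generate a synthetic reference sequence with planted repeat tracts
#'
#' A random ACGT background with non-overlapping repeat tracts planted at
#' random positions.  Flanking bases are chosen so that each planted tract
#' cannot extend beyond its planned boundaries.
#'
#' @param seed Integer seed.
#' @param length Chromosome length in bp.
#' @param repeat_spec Data frame with columns `unit`, `tract_length`,
#'   `count` describing tracts to plant (may be empty).
#' @param chrom Chromosome name (default `"chr1"`).
#' @return List with `seq` (named character vector) and `planted` (repeat
#'   table of the planted tracts).
#' @export
generate_reference <- function(seed, length, repeat_spec = NULL,
                               chrom = "chr1") {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    x <- sample(bases, length, replace = TRUE)
    planted <- list()
    occupied <- logical(length)
    if (!is.null(repeat_spec) && nrow(repeat_spec) > 0) {
      total_needed <- sum((repeat_spec$tract_length + 2) * repeat_spec$count)
      if (total_needed > length / 2) stop("repeat_spec does not fit in length")
      for (i in seq_len(nrow(repeat_spec))) {
        unit <- toupper(repeat_spec$unit[i])
        tl <- repeat_spec$tract_length[i]
        u <- nchar(unit)
        uvec <- strsplit(unit, "")[[1]]
        for (j in seq_len(repeat_spec$count[i])) {
          placed <- FALSE
          for (attempt in 1:200) {
            start <- sample.int(length - tl - 2L, 1L) + 1L
            span <- (start - 1L):(start + tl)
            if (any(occupied[span])) next
            tract <- rep(uvec, length.out = tl)
            x[start:(start + tl - 1L)] <- tract
            # flanks must break the repeat pattern on both sides
            left_break <- uvec[u]  # base that would extend the tract leftward
            right_break <- uvec[(tl %% u) + 1L]
            x[start - 1L] <- sample(setdiff(bases, left_break), 1L)
            x[start + tl] <- sample(setdiff(bases, right_break), 1L)
            occupied[span] <- TRUE
            planted[[length(planted) + 1L]] <-
              data.frame(chrom = chrom, start = start,
                         end = start + tl - 1L, unit = unit,
                         tract_length = tl, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!placed) stop("could not place repeat tract (spec unfittable)")
        }
      }
    }
    seq <- paste(x, collapse = "")
    names(seq) <- chrom
    planted_df <- if (length(planted)) do.call(rbind, planted) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 unit = character(0), tract_length = integer(0),
                 stringsAsFactors = FALSE)
    planted_df <- planted_df[order(planted_df$start), , drop = FALSE]
    rownames(planted_df) <- NULL
    list(seq = seq, planted = planted_df)
  })
}

#' Default parameters for synthetic ancestor/descendant pairs
#'
#' The defaults describe a diploid mutation-accumulation sample sequenced
#' to ~50x: Gaussian depth (mean 50, sd 7), log-normal strand bias (sd 0.2
#' on the natural-log ratio), a logistic slippage error model
#' (M = 0.001, L = 0.15, k = 0.9, x0 = 10 for homopolymers, with the
#' take-off length scaling with unit length so that slippage depends on the
#' number of repeated units), a per-read substitution noise rate of 0.002,
#' and 60% of reads fully traversing a repeat tract.
#'
#' @param ... Overrides for any default element.
#' @return Named list of generator parameters.
#' @export
synthetic_params <- function(...) {
  defaults <- list(
    ploidy = 2L,
    depth_mean = 50,
    depth_sd = 7,
    bias_sd = 0.2,
    substitution_error = 0.002,
    noise_sites_per_mb = 500,
    min_candidate_reads = 3L,
    traversing_fraction = 0.6,
    indel_logistic = list(insertion = c(M = 5e-4, L = 0.08, k = 0.9, x0 = 10),
                          deletion = c(M = 1e-3, L = 0.15, k = 0.9, x0 = 10)),
    end_bias = NULL,          # optional depth_correction_model-like list
    abnormal_regions = NULL,  # optional data.frame chrom,start,end,multiplier
    mode = "sample"           # or "expected" for deterministic counts
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  defaults
}

# True indel error model built from the generator's logistic parameters:
# the same object the estimation side produces, closing the loop between
# generation and inference.  Slippage requires repeated units in register,
# so rates track the number of units rather than bp: the unit-length-u curve
# is the unit-1 curve evaluated in units, i.e. x0 scaled by u and k by 1/u
# on the bp axis.
true_indel_model <- function(params) {
  fits <- list()
  for (event in c("insertion", "deletion")) {
    cf <- params$indel_logistic[[event]]
    for (u in 1:4) {
      fits[[paste(event, u, sep = "_")]] <-
        structure(list(event = event, unit_length = u,
                       M = unname(cf["M"]), L = unname(cf["L"]),
                       k = unname(cf["k"]) / u, x0 = unname(cf["x0"]) * u,
                       fitted_lengths = integer(0)),
                  class = "indel_error_fit")
    }
  }
  structure(list(rates = NULL, fits = fits), class = "indel_error_model")
}

#' Choose planted mutation sites on a synthetic reference
#'
#' Substitutions are placed at positions outside repeat tracts; single-unit
#' insertion/deletion mutations are placed at randomly chosen repeat tracts
#' no longer than `max_tract_length`.
#'
#' @param reference A [generate_reference()] result.
#' @param repeats Repeat table for the reference (e.g. [find_repeats()]).
#' @param n_substitutions,n_indels Numbers of planted events.
#' @param fraction Clonal fraction `1`, or a subclonal fraction
#'   (0.5/0.25/0.125), recycled over mutations.
#' @param max_tract_length Longest tract eligible for an indel (default 10).
#' @param seed Integer seed.
#' @return Data frame `chrom`, `pos`, `kind`, `ref`, `alt`, `fraction`.
#' @export
plant_mutations <- function(reference, repeats, n_substitutions, n_indels,
                            fraction = 1, max_tract_length = 10L, seed = 1L) {
  chrom <- names(reference$seq)[1]
  seq <- reference$seq[[1]]
  L <- nchar(seq)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    in_repeat <- logical(L)
    for (i in seq_len(nrow(repeats))) {
      in_repeat[(max(repeats$start[i] - 1L, 1L)):(min(repeats$end[i] + 1L, L))] <- TRUE
    }
    free <- setdiff(which(!in_repeat), c(1:2, (L - 1):L))
    if (length(free) < n_substitutions) stop("not enough non-repeat positions")
    sub_pos <- sort(sample(free, n_substitutions))
    subs <- do.call(rbind, lapply(sub_pos, function(p) {
      ref <- substr(seq, p, p)
      data.frame(chrom = chrom, pos = p, kind = "substitution", ref = ref,
                 alt = sample(setdiff(bases, ref), 1L),
                 stringsAsFactors = FALSE)
    }))
    elig <- which(repeats$tract_length <= max_tract_length &
                    repeats$tract_length >= nchar(repeats$unit) + 4L)
    if (length(elig) < n_indels) stop("not enough eligible repeat tracts")
    idx <- sort(sample(elig, n_indels))
    indels <- do.call(rbind, lapply(idx, function(i) {
      tract <- substr(seq, repeats$start[i], repeats$end[i])
      u <- repeats$unit[i]
      del <- stats::runif(1) < 0.5
      alt <- if (del) substr(tract, 1L, nchar(tract) - nchar(u)) else
        paste0(tract, u)
      data.frame(chrom = chrom, pos = repeats$start[i],
                 kind = if (del) "deletion" else "insertion",
                 ref = tract, alt = alt, stringsAsFactors = FALSE)
    }))
    mut <- rbind(subs, indels)
    if (is.null(mut)) {
      mut <- data.frame(chrom = character(0), pos = integer(0),
                        kind = character(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE)
    }
    mut$fraction <- rep_len(fraction, nrow(mut))
    mut <- mut[order(mut$pos), , drop = FALSE]
    rownames(mut) <- NULL
    mut
  })
}

#' Generate a synthetic t0/outgrowth pair with known truth
#'
#' Produces per-sample depth tracks, a strand-specific counts table over
#' candidate sites, per-tract traversing-coverage observations, and a truth
#' manifest.  Candidate sites comprise every planted mutation site, repeat
#' tracts where at least `min_candidate_reads` slippage error reads were
#' drawn across the two samples, and random substitution-noise sites with
#' at least that many noise reads — emulating the candidate-site density of
#' a sensitive local-reassembly caller, which emits a site only when some
#' reads support an alternative allele.  Counts are drawn per strand: the strand split follows the
#' log-normal strand-bias model, and within a strand allele counts are
#' multinomial at the error-corrected true frequencies.  With
#' `mode = "expected"` counts are deterministic rounded expectations.
#'
#' @param reference A [generate_reference()] result (or named character
#'   vector of sequences).
#' @param mutations Planted mutation data frame (see [plant_mutations()]);
#'   may be empty.
#' @param params [synthetic_params()] list.
#' @param seed Integer seed.
#' @param sample_names Length-2 character vector: t0 then outgrowth.
#' @param repeats Optional precomputed repeat table for the reference
#'   (recomputed with [find_repeats()] when `NULL`).
#' @return List with `sites`, `depth` (named list of depth tracks),
#'   `repeat_obs` (named list of per-tract observation data frames),
#'   `repeats`, `truth` (manifest), `samples`, `genome_length`.
#' @export
generate_pair <- function(reference, mutations = NULL,
                          params = synthetic_params(), seed = 1L,
                          sample_names = c("t0", "outgrowth"),
                          repeats = NULL) {
  if (is.character(reference)) reference <- list(seq = reference)
  seq <- reference$seq
  chrom <- names(seq)[1]
  L <- nchar(seq[[1]])
  if (is.null(repeats)) repeats <- find_repeats(seq)
  truth_model <- true_indel_model(params)
  expected_mode <- identical(params$mode, "expected")
  if (is.null(mutations)) {
    mutations <- data.frame(chrom = character(0), pos = integer(0),
                            kind = character(0), ref = character(0),
                            alt = character(0), fraction = numeric(0),
                            stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    # -- depth tracks --------------------------------------------------------
    depth_for <- function() {
      d <- if (expected_mode) rep(params$depth_mean, L) else
        stats::rnorm(L, params$depth_mean, params$depth_sd)
      if (!is.null(params$end_bias)) {
        pos <- seq_len(L)
        d <- d * depth_correction_factor(params$end_bias,
                                         pmin(pos, L - pos + 1L))
      }
      ab <- params$abnormal_regions
      if (!is.null(ab)) {
        for (i in seq_len(nrow(ab))) {
          span <- max(ab$start[i], 1L):min(ab$end[i], L)
          d[span] <- d[span] * ab$multiplier[i]
        }
      }
      pmax(round(d), 0)
    }
    depth <- list(depth_for(), depth_for())
    names(depth) <- sample_names

    # -- per-tract traversing coverage and slippage error reads --------------
    n_rep <- nrow(repeats)
    mut_tract <- repeats$start %in% mutations$pos[mutations$kind != "substitution"]
    obs <- list()
    err_reads <- list()
    for (s in sample_names) {
      trav <- round(params$traversing_fraction * depth[[s]][repeats$start])
      trav <- pmax(trav, 0)
      ul <- nchar(repeats$unit)
      rate_vec <- function(event) {
        r <- numeric(n_rep)
        for (u in unique(ul)) {
          idx <- ul == u
          fit <- truth_model$fits[[paste(event, u, sep = "_")]]
          r[idx] <- expected_error_rate(fit, repeats$tract_length[idx])
        }
        r
      }
      r_ins <- rate_vec("insertion")
      r_del <- rate_vec("deletion")
      if (expected_mode) {
        ins_reads <- round(trav * r_ins)
        del_reads <- round(trav * r_del)
      } else {
        ins_reads <- stats::rbinom(n_rep, trav, r_ins)
        del_reads <- stats::rbinom(n_rep, trav, r_del)
      }
      obs[[s]] <- data.frame(chrom = repeats$chrom, start = repeats$start,
                             end = repeats$end, unit = repeats$unit,
                             tract_length = repeats$tract_length,
                             traversing_coverage = trav,
                             insertions = ins_reads, deletions = del_reads,
                             stringsAsFactors = FALSE)
      err_reads[[s]] <- ins_reads + del_reads
    }

    # -- candidate sites -----------------------------------------------------
    max_sites <- nrow(mutations) + n_rep +
      ceiling(params$noise_sites_per_mb * L / 1e6) + 8L
    sites <- vector("list", max_sites)
    n_sites <- 0L
    add_site <- function(pos, alleles, freq_list, keep_alleles = alleles[1]) {
      # strand bias is a locus property (local mapping context), shared by
      # the isogenic samples; binomial read sampling adds per-sample noise
      lr <- if (expected_mode) 0 else stats::rnorm(1, 0, params$bias_sd)
      counts <- lapply(sample_names, function(s) {
        draw_site_counts(depth[[s]][pos], freq_list[[s]], alleles,
                         lr, expected_mode)
      })
      names(counts) <- sample_names
      # a variant caller only reports alleles with read support
      supported <- colSums(counts[[1]]) + colSums(counts[[2]]) > 0
      keep <- alleles %in% keep_alleles | supported
      alleles <- alleles[keep]
      counts <- lapply(counts, function(m) m[, keep, drop = FALSE])
      n_sites <<- n_sites + 1L
      sites[[n_sites]] <<- list(chrom = chrom, pos = as.integer(pos),
                                alleles = alleles, counts = counts)
    }
    corrected <- function(genotype_freq, tract_i) {
      ctx <- list(unit = repeats$unit[tract_i],
                  unit_length = nchar(repeats$unit[tract_i]),
                  ref_allele = names(genotype_freq)[1],
                  ref_tract_length = repeats$tract_length[tract_i])
      correct_for_indel_error(genotype_freq, ctx, truth_model)
    }

    # planted mutations
    for (i in seq_len(nrow(mutations))) {
      mu <- mutations[i, ]
      f_alt <- if (mu$fraction >= 1) 1 / params$ploidy else
        mu$fraction / params$ploidy
      t0_freq <- stats::setNames(c(1, 0), c(mu$ref, mu$alt))
      out_freq <- stats::setNames(c(1 - f_alt, f_alt), c(mu$ref, mu$alt))
      if (mu$kind != "substitution") {
        ti <- which(repeats$start == mu$pos)[1]
        t0_freq <- corrected(t0_freq, ti)
        out_freq <- corrected(out_freq, ti)
      }
      alleles <- union(mu$ref, union(names(t0_freq), names(out_freq)))
      t0_freq <- freq_over(t0_freq, alleles)
      out_freq <- freq_over(out_freq, alleles)
      fl <- list(t0_freq, out_freq); names(fl) <- sample_names
      add_site(mu$pos, alleles, fl, keep_alleles = c(mu$ref, mu$alt))
    }

    # repeat tracts with at least one drawn error read in either sample
    err_any <- err_reads[[1]] + err_reads[[2]] >= params$min_candidate_reads
    for (ti in which(err_any & !mut_tract)) {
      tract <- substr(seq[[1]], repeats$start[ti], repeats$end[ti])
      base_freq <- stats::setNames(1, tract)
      f <- corrected(base_freq, ti)
      alleles <- c(tract, setdiff(names(f), tract))
      f <- freq_over(f, alleles)
      fl <- list(f, f); names(fl) <- sample_names
      add_site(repeats$start[ti], alleles, fl)
    }

    # substitution-noise sites
    bases <- c("A", "C", "G", "T")
    n_noise <- round(params$noise_sites_per_mb * L / 1e6)
    if (n_noise > 0 && !expected_mode) {
      in_repeat <- logical(L)
      for (i in seq_len(n_rep)) {
        in_repeat[repeats$start[i]:repeats$end[i]] <- TRUE
      }
      cand <- setdiff(which(!in_repeat), mutations$pos)
      noise_pos <- sort(sample(cand, min(n_noise, length(cand))))
      eps <- params$substitution_error
      pre_t0 <- stats::rbinom(length(noise_pos), depth[[1]][noise_pos], eps)
      pre_out <- stats::rbinom(length(noise_pos), depth[[2]][noise_pos], eps)
      keep <- pre_t0 + pre_out >= params$min_candidate_reads
      for (j in which(keep)) {
        p <- noise_pos[j]
        ref <- substr(seq[[1]], p, p)
        alt <- sample(setdiff(bases, ref), 1L)
        alleles <- c(ref, alt)
        f <- stats::setNames(c(1 - eps, eps), alleles)
        fl <- list(f, f); names(fl) <- sample_names
        add_site(p, alleles, fl)
      }
    }

    sites <- sites[seq_len(n_sites)]
    ord <- order(vapply(sites, `[[`, integer(1), "pos"))
    sites <- sites[ord]

    list(sites = sites, depth = depth, repeat_obs = obs, repeats = repeats,
         truth = list(mutations = mutations, params = params, seed = seed),
         samples = data.frame(name = sample_names,
                              role = c("t0", "outgrowth"),
                              ploidy = params$ploidy,
                              stringsAsFactors = FALSE),
         genome_length = L)
  })
}

freq_over <- function(freq, alleles) {
  out <- stats::setNames(numeric(length(alleles)), alleles)
  out[names(freq)] <- freq
  out
}

# Draw one sample's 2 x n_alleles strand count matrix at a site, given the
# site's (shared) log strand-bias ratio.
draw_site_counts <- function(depth, freqs, alleles, lr, expected_mode) {
  n <- length(alleles)
  m <- matrix(0L, nrow = 2, ncol = n,
              dimnames = list(c("top", "bottom"), alleles))
  if (depth <= 0) return(m)
  if (expected_mode) {
    top <- round(depth / 2)
    m["top", ] <- round_preserving_sum(freqs * top)
    m["bottom", ] <- round_preserving_sum(freqs * (depth - top))
    return(m)
  }
  top <- stats::rbinom(1, depth, 1 / (1 + exp(-lr)))
  m["top", ] <- draw_multinomial(top, freqs)
  m["bottom", ] <- draw_multinomial(depth - top, freqs)
  m
}

draw_multinomial <- function(n, freqs) {
  if (n == 0) return(integer(length(freqs)))
  as.integer(stats::rmultinom(1, n, pmax(freqs, 0)))
}

# Round to integers while preserving the (rounded) total: floor plus
# largest-remainder allocation.
round_preserving_sum <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Write a synthetic pair to disk as standard pipeline inputs
#'
#' Emits a FASTA reference, sample sheet, counts table, per-sample
#' bedGraph depth tracks and per-sample repeat observation tables.
#'
#' @param pair A [generate_pair()] result.
#' @param reference The reference used to generate `pair`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the sample sheet path.
#' @export
write_dataset <- function(pair, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(reference)) reference <- list(seq = reference)
  fa <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(reference$seq)
  Biostrings::writeXStringSet(dna, fa)
  counts_path <- file.path(dir, "counts.tsv")
  write_counts_table(pair$sites, counts_path)
  sheet <- pair$samples
  sheet$counts_path <- counts_path
  sheet$depth_path <- file.path(dir, paste0("depth_", sheet$name, ".bedGraph"))
  sheet$repeat_obs_path <- file.path(dir, paste0("repeat_obs_", sheet$name,
                                                 ".tsv"))
  for (i in seq_len(nrow(sheet))) {
    s <- sheet$name[i]
    track <- list(pair$depth[[s]])
    names(track) <- names(reference$seq)[1]
    write_bedgraph(track, sheet$depth_path[i])
    utils::write.table(pair$repeat_obs[[s]], sheet$repeat_obs_path[i],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pair$truth$mutations,
                     file.path(dir, "truth_mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sheet_path)
}
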