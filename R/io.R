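#' Read a sample sheet
#'
#' The sample sheet is a tab-delimited file with a header row and one row per
#' sample.  Required columns: `name`, `role` (`t0` or `outgrowth`), `ploidy`
#' (integer >= 1).  Optional columns: `generations` (outgrowth only),
#' `counts_path`, `depth_path`, `repeat_obs_path`.  Exactly one sample must
#' have role `t0`; every outgrowth is compared against it.
#'
#' @param path Path to the sample sheet.
#' @return A `data.frame` of validated sample configurations, one row per
#'   sample, with class `"sample_sheet"`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df A data frame with the sample sheet columns (used when samples
#'   are constructed in code rather than read from disk).
#' @export
validate_sample_sheet <- function(df) {
  required <- c("name", "role", "ploidy")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate sample name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(df$role), c("t0", "outgrowth"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         " (must be 't0' or 'outgrowth')")
  }
  n_t0 <- sum(df$role == "t0")
  if (n_t0 == 0L) stop("sample sheet must contain exactly one t0 sample; found none")
  if (n_t0 > 1L) stop("multiple t0 samples in sample sheet")
  pl <- suppressWarnings(as.numeric(df$ploidy))
  if (any(is.na(pl)) || any(pl != round(pl)) || any(pl < 1)) {
    stop("ploidy must be an integer >= 1 for every sample")
  }
  df$ploidy <- as.integer(pl)
  if (!"generations" %in% names(df)) df$generations <- NA_real_
  df$generations <- suppressWarnings(as.numeric(df$generations))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

# -- counts tables ------------------------------------------------------------

#' Read a strand-specific allele counts table
#'
#' The counts table is tab-delimited with header
#' `chrom  pos  alleles  <sample1>  <sample2> ...`.  `alleles` is a
#' comma-separated list of allele sequences with the reference allele first;
#' each sample cell holds one `top:bottom` read-count pair per allele,
#' comma-separated in allele order.  Positions are 1-based.
#'
#' @param path Path to the counts table.
#' @param samples Character vector of sample names that must be present.
#' @return A list of site objects in coordinate order.  Each site is a list
#'   with `chrom`, `pos`, `alleles` (reference first) and `counts`, a named
#'   list mapping sample name to a 2 x n_alleles integer matrix with rows
#'   `top` and `bottom`.
#' @export
read_counts_table <- function(path, samples) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (!all(c("chrom", "pos", "alleles") %in% names(df))) {
    stop("counts table must have columns chrom, pos, alleles")
  }
  missing <- setdiff(samples, names(df))
  if (length(missing)) {
    stop("counts table is missing sample column(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  sites <- vector("list", n)
  allele_lists <- strsplit(df$alleles, ",", fixed = TRUE)
  parsed <- lapply(samples, function(s) strsplit(df[[s]], ",", fixed = TRUE))
  names(parsed) <- samples
  for (i in seq_len(n)) {
    alleles <- allele_lists[[i]]
    if (any(!grepl("^[ACGT]+$", alleles))) {
      stop("invalid allele string at ", df$chrom[i], ":", df$pos[i])
    }
    counts <- lapply(samples, function(s) {
      pairs <- parsed[[s]][[i]]
      if (length(pairs) != length(alleles)) {
        stop("allele/count arity mismatch for sample ", s, " at ",
             df$chrom[i], ":", df$pos[i])
      }
      mat <- vapply(strsplit(pairs, ":", fixed = TRUE), function(p) {
        if (length(p) != 2L) stop("malformed top:bottom pair at ",
                                  df$chrom[i], ":", df$pos[i])
        v <- suppressWarnings(as.integer(p))
        if (any(is.na(v)) || any(v < 0)) {
          stop("negative or non-integer count at ", df$chrom[i], ":", df$pos[i])
        }
        v
      }, integer(2))
      rownames(mat) <- c("top", "bottom")
      colnames(mat) <- alleles
      mat
    })
    names(counts) <- samples
    sites[[i]] <- list(chrom = df$chrom[i], pos = as.integer(df$pos[i]),
                       alleles = alleles, counts = counts)
  }
  ord <- order(vapply(sites, `[[`, character(1), "chrom"),
               vapply(sites, `[[`, integer(1), "pos"))
  sites[ord]
}

#' Write a counts table
#'
#' @param sites List of site objects as produced by [read_counts_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts_table <- function(sites, path) {
  if (length(sites) == 0L) {
    writeLines("chrom\tpos\talleles", path)
    return(invisible(path))
  }
  samples <- names(sites[[1]]$counts)
  lines <- vapply(sites, function(site) {
    cells <- vapply(samples, function(s) {
      m <- site$counts[[s]]
      paste(paste0(m["top", ], ":", m["bottom", ]), collapse = ",")
    }, character(1))
    paste(c(site$chrom, site$pos, paste(site$alleles, collapse = ","), cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("chrom", "pos", "alleles", samples), collapse = "\t"),
               lines), path)
  invisible(path)
}

# -- depth tracks (bedGraph) --------------------------------------------------

#' Read a bedGraph file into a per-position depth track
#'
#' Intervals are 0-based half-open on disk; the returned track is a named
#' list of per-position numeric vectors with 1-based indexing.
#'
#' @param path Path to the bedGraph file.
#' @param chrom_lengths Optional named integer vector of chromosome lengths;
#'   when omitted each chromosome's length is taken as the largest interval
#'   end observed.
#' @return A named list mapping chromosome to a numeric vector of depths.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(structure(list(), names = character(0)))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  if (any(gr$score < 0)) stop("negative depth value in bedGraph")
  track <- list()
  for (chrom in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    g <- g[order(GenomicRanges::start(g))]
    st <- GenomicRanges::start(g); en <- GenomicRanges::end(g)
    if (any(st[-1] <= en[-length(en)])) stop("overlapping intervals in bedGraph for ", chrom)
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else max(en)
    v <- numeric(len)
    v[unlist(Map(seq.int, st, en))] <- rep(g$score, en - st + 1L)
    track[[chrom]] <- v
  }
  track
}

#' Write a depth track as run-length-compressed bedGraph
#'
#' @param track Named list mapping chromosome to per-position depths.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  runs <- lapply(names(track), function(chrom) {
    r <- rle(track[[chrom]])
    ends <- cumsum(r$lengths)
    data.frame(chrom = chrom, start = ends - r$lengths + 1L, end = ends,
               score = r$values, stringsAsFactors = FALSE)
  })
  if (length(runs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  d <- do.call(rbind, runs)
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                               score = d$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# -- BED intervals ------------------------------------------------------------

#' Read a BED file of intervals
#'
#' @param path Path to a BED file (0-based half-open intervals).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open, as on disk) and, if present, `name`.  An empty or absent
#'   fourth column yields `NA` names.
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name` (used e.g. for per-interval copy numbers).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  if ("name" %in% names(df)) gr$name <- as.character(df$name)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a copy-number map from a BED-like file
#'
#' The fourth (name) column carries the integer copy number of each interval;
#' positions outside any interval default to the sample ploidy.
#'
#' @param path Path to the BED file.
#' @return A `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   and integer `copy_number`; intervals must not overlap within a
#'   chromosome.
#' @export
read_copy_number_map <- function(path) {
  df <- read_bed(path)
  cn <- suppressWarnings(as.integer(df$name))
  if (nrow(df) > 0 && (any(is.na(cn)) || any(cn < 1))) {
    stop("copy-number map requires an integer >= 1 in the 4th BED column")
  }
  df$copy_number <- cn
  df$name <- NULL
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping copy-number intervals on ", chrom)
    }
  }
  df
}

# -- allelic fraction histogram ----------------------------------------------

#' Allelic-fraction histogram for ploidy assessment
#'
#' For every site with non-zero depth in `sample`, the fraction of reads
#' supporting each allele (pooled over strands) is accumulated into a
#' histogram over \[0, 1\].  In a largely homozygous genome the interior
#' peaks sit near multiples of 1/ploidy, so the histogram gives a quick
#' visual estimate of global ploidy.
#'
#' @param sites List of site objects (see [read_counts_table()]).
#' @param sample Sample name.
#' @param n_bins Number of bins (default 100).
#' @return List with `breaks` (length `n_bins + 1`), `counts` (per-bin
#'   observation counts) and `skipped` (number of zero-depth sites skipped).
#' @export
allelic_fraction_histogram <- function(sites, sample, n_bins = 100L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- integer(n_bins)
  skipped <- 0L
  for (site in sites) {
    m <- site$counts[[sample]]
    if (is.null(m)) stop("sample ", sample, " absent from site counts")
    tot <- sum(m)
    if (tot == 0) {
      skipped <- skipped + 1L
      next
    }
    frac <- colSums(m) / tot
    bin <- pmin(pmax(ceiling(frac * n_bins), 1L), n_bins)
    for (b in bin) counts[b] <- counts[b] + 1L
  }
  list(breaks = breaks, counts = counts, skipped = skipped)
}
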