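#' Find simple repeat tracts in a reference sequence
#'
#' Enumerates all maximal simple repeats with unit length 1-4 and total
#' tract length >= 4 bp.  Tracts whose unit could be reconstructed by
#' concatenating a shorter unit (e.g. "ATAT", reducible to "AT") are
#' eliminated, as is any tract wholly contained within another tract of the
#' same unit or a circular permutation thereof.  Tracts may end in a partial
#' trailing unit; the partial bases count toward the tract length, which is
#' the length axis used by the indel error model.  Soft-masked (lowercase)
#' bases are uppercased before scanning; `N` bases break tracts.
#'
#' @param reference Named character vector of chromosome sequences (or a
#'   single unnamed sequence, reported as chromosome `"chr1"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `unit` and `tract_length`, sorted by chromosome and start.
#' @export
find_repeats <- function(reference) {
  if (is.null(names(reference))) {
    names(reference) <- paste0("chr", seq_along(reference))
  }
  out <- lapply(names(reference), function(chrom) {
    find_repeats_one(toupper(reference[[chrom]]), chrom)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      tract_length = integer(0), stringsAsFactors = FALSE))
  }
  res <- res[order(res$chrom, res$start, nchar(res$unit), res$unit), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

find_repeats_one <- function(seq, chrom) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(!x %in% c("A", "C", "G", "T", "N"))) {
    stop("non-ACGTN symbol in reference sequence for ", chrom)
  }
  n <- length(x)
  has_n <- x == "N"
  n_before <- cumsum(has_n)  # count of N bases in x[1..i]
  parts <- vector("list", 4L)
  for (k in 1:4) {
    if (n <= k) next
    a <- x[seq_len(n - k)]
    b <- x[seq_len(n - k) + k]
    eq <- a == b & a != "N"
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    sel <- r$values & (r$lengths + k) >= 4L
    start <- run_start[sel]
    end <- run_end[sel] + k
    # a tract must be N-free
    ok <- (n_before[end] - ifelse(start > 1L, n_before[start - 1L], 0L)) == 0L
    start <- start[ok]; end <- end[ok]
    if (!length(start)) next
    unit <- substring(seq, start, start + k - 1L)
    uu <- unique(unit)
    prim <- vapply(uu, unit_is_primitive, logical(1))[match(unit, uu)]
    if (!any(prim)) next
    parts[[k]] <- data.frame(chrom = chrom, start = start[prim],
                             end = end[prim], unit = unit[prim],
                             tract_length = end[prim] - start[prim] + 1L,
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(df) || nrow(df) == 0L) return(NULL)
  drop_contained_tracts(df)
}

# A unit is primitive iff it is not a whole-number repetition of a shorter
# unit.
unit_is_primitive <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(unit, 1L, d), k / d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

canonical_rotation <- function(unit) {
  k <- nchar(unit)
  rots <- vapply(seq_len(k), function(i) {
    paste0(substr(unit, i, k), substr(unit, 1L, i - 1L))
  }, character(1))
  min(rots)
}

# Drop tracts wholly contained in another tract whose unit is the same or a
# circular permutation (ties between phases keep the leftmost, longest tract).
# Within a rotation class, after sorting by (start asc, end desc) a tract is
# contained in an earlier one iff its end does not exceed the running maximum
# of earlier ends.
drop_contained_tracts <- function(df) {
  units <- unique(df$unit)
  rot_map <- stats::setNames(vapply(units, canonical_rotation, character(1)),
                             units)
  rot <- rot_map[df$unit]
  keep <- rep(TRUE, nrow(df))
  for (key in unique(rot)) {
    idx <- which(rot == key)
    if (length(idx) < 2L) next
    ord <- idx[order(df$start[idx], -df$end[idx])]
    ends <- df$end[ord]
    prior_max <- cummax(c(-1L, ends[-length(ends)]))
    keep[ord] <- ends > prior_max
    keep[ord[1]] <- TRUE
  }
  df[keep, , drop = FALSE]
}

#' Draw a random sample of repeat tracts
#'
#' Uniform sampling without replacement; reduces the memory needed to fit
#' the indel error model on large genomes.  Deterministic for a fixed seed.
#'
#' @param repeats Repeat table from [find_repeats()].
#' @param n Number of tracts to keep (`min(n, nrow(repeats))` are returned).
#' @param seed Integer seed.
#' @return A subset of `repeats`, in genomic order.
#' @export
sample_repeats <- function(repeats, n, seed) {
  if (n < 0) stop("n must be >= 0")
  n <- min(n, nrow(repeats))
  idx <- with_seed(seed, sample.int(nrow(repeats), n))
  out <- repeats[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write repeat tract tables
#'
#' Tab-delimited files with columns `chrom`, `start`, `end`, `unit`,
#' `tract_length` (1-based inclusive coordinates).
#'
#' @param repeats Repeat table.
#' @param path File path.
#' @return `read_repeat_file` returns the repeat table; `write_repeat_file`
#'   returns `path` invisibly.
#' @export
write_repeat_file <- function(repeats, path) {
  utils::write.table(repeats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_repeat_file
#' @export
read_repeat_file <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
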