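# Shared builders and independent oracles used across the suite.

with_seed <- function(seed, code) {
  set.seed(seed)
  code
}

# 2 x n strand count matrix
cmat <- function(top, bottom, alleles) {
  m <- rbind(top = top, bottom = bottom)
  colnames(m) <- alleles
  storage.mode(m) <- "integer"
  m
}

make_site <- function(pos, alleles, ..., chrom = "chr1") {
  counts <- list(...)
  list(chrom = chrom, pos = as.integer(pos), alleles = alleles,
       counts = counts)
}

# Independent brute-force repeat enumerator: try every (start, unit length),
# extend rightward while the pattern continues, then apply the elimination
# rules from first principles.
brute_force_repeats <- function(seq, chrom = "chr1") {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  cands <- list()
  for (k in 1:4) {
    for (start in seq_len(max(n - k, 0))) {
      unit <- x[start:(start + k - 1L)]
      if (any(unit == "N")) next
      end <- start + k - 1L
      while (end + 1L <= n && x[end + 1L] != "N" &&
             x[end + 1L] == x[end + 1L - k]) {
        end <- end + 1L
      }
      len <- end - start + 1L
      if (len < 4L || len < k + 1L) next  # must repeat beyond one bare unit
      # primitive unit check
      ustr <- paste(unit, collapse = "")
      primitive <- TRUE
      for (d in seq_len(k - 1L)) {
        if (k %% d == 0L && strrep(substr(ustr, 1, d), k / d) == ustr) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      cands[[length(cands) + 1L]] <- list(start = start, end = end,
                                          unit = ustr, k = k)
    }
  }
  if (!length(cands)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      tract_length = integer(0), stringsAsFactors = FALSE))
  }
  rot_class <- function(u) {
    k <- nchar(u)
    min(vapply(seq_len(k), function(i) {
      paste0(substr(u, i, k), substr(u, 1, i - 1L))
    }, character(1)))
  }
  keep <- rep(TRUE, length(cands))
  for (i in seq_along(cands)) {
    for (j in seq_along(cands)) {
      if (i == j) next
      a <- cands[[i]]; b <- cands[[j]]
      if (nchar(a$unit) != nchar(b$unit)) next
      if (rot_class(a$unit) != rot_class(b$unit)) next
      same <- a$start == b$start && a$end == b$end
      inside <- a$start >= b$start && a$end <= b$end
      if (inside && !same) { keep[i] <- FALSE; break }
      if (same && j < i) { keep[i] <- FALSE; break }  # keep first phase
    }
  }
  cands <- cands[keep]
  df <- data.frame(chrom = chrom,
                   start = vapply(cands, `[[`, integer(1), "start"),
                   end = vapply(cands, `[[`, integer(1), "end"),
                   unit = vapply(cands, `[[`, character(1), "unit"),
                   stringsAsFactors = FALSE)
  df$tract_length <- df$end - df$start + 1L
  df <- unique(df)
  df <- df[order(df$start, nchar(df$unit), df$unit), ]
  rownames(df) <- NULL
  df
}

# Independent brute-force genotype search: enumerate all models from first
# principles with expand.grid, score with the published formulas, return the
# minimum score (ties unresolved; used to check score optimality).
brute_force_min_score <- function(counts, alleles, copy_number) {
  total <- sum(counts)
  pooled <- colSums(counts)
  grids <- expand.grid(rep(list(seq_along(alleles)), copy_number))
  clonals <- unique(lapply(seq_len(nrow(grids)), function(i) {
    sort(alleles[as.integer(grids[i, ])])
  }))
  models <- list()
  for (g in clonals) {
    models[[length(models) + 1L]] <- list(clonal = g, fraction = NA_real_)
    for (pos_i in seq_along(g)) {
      for (b in setdiff(alleles, g[pos_i])) {
        sub <- sort(c(g[-pos_i], b))
        for (f in c(0.5, 0.25, 0.125)) {
          models[[length(models) + 1L]] <-
            list(clonal = g, sub = sub, fraction = f)
        }
      }
    }
  }
  scores <- vapply(models, function(m) {
    e <- stats::setNames(numeric(length(alleles)), alleles)
    tab <- table(m$clonal)
    if (is.na(m$fraction)) {
      e[names(tab)] <- as.numeric(tab) / copy_number
    } else {
      e[names(tab)] <- (1 - m$fraction) * as.numeric(tab) / copy_number
      stab <- table(m$sub)
      e[names(stab)] <- e[names(stab)] +
        m$fraction * as.numeric(stab) / copy_number
    }
    e[e == 0] <- 2 / total
    o <- pooled / total
    o[o == 0] <- 2 / total
    sum(abs(log(o / e)))
  }, numeric(1))
  min(scores)
}

# Independent brute-force shortest mutation paths: enumerate every event
# sequence up to a depth limit.
brute_force_paths <- function(g0, g1, alleles, max_depth = 4L) {
  g0 <- sort(g0); g1 <- sort(g1)
  key <- function(g) paste(g, collapse = "|")
  events_from <- function(g) {
    evs <- list()
    for (a in unique(g)) {
      for (b in setdiff(alleles, a)) {
        evs[[length(evs) + 1L]] <- list(kind = "conversion", from = a, to = b)
      }
    }
    for (b in alleles) {
      evs[[length(evs) + 1L]] <- list(kind = "gain", from = NA, to = b)
    }
    if (length(g) > 1) {
      for (a in unique(g)) {
        evs[[length(evs) + 1L]] <- list(kind = "loss", from = a, to = NA)
      }
    }
    evs
  }
  apply_ev <- function(g, ev) {
    if (ev$kind == "conversion") {
      g <- g[-match(ev$from, g)]
      sort(c(g, ev$to))
    } else if (ev$kind == "gain") {
      sort(c(g, ev$to))
    } else {
      sort(g[-match(ev$from, g)])
    }
  }
  found <- list()
  recurse <- function(g, path, depth) {
    if (key(g) == key(g1)) {
      found[[length(found) + 1L]] <<- path
      return()
    }
    if (depth == 0L) return()
    for (ev in events_from(g)) {
      recurse(apply_ev(g, ev), c(path, list(ev)), depth - 1L)
    }
  }
  for (d in 0:max_depth) {
    found <- list()
    recurse(g0, list(), d)
    found <- Filter(function(p) length(p) == d, found)
    if (length(found)) return(found)
  }
  list()
}
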