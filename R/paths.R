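# Mutation events are lists: list(kind, from, to) with kind one of
# "conversion" (rewrites one allele copy), "gain" (adds a copy of any
# observed allele) or "loss" (removes one copy of a present allele).

event_key <- function(ev) paste(ev$kind, ev$from, ev$to, sep = "\r")

apply_event <- function(genotype, ev) {
  switch(ev$kind,
    conversion = sort(c(multiset_diff(genotype, ev$from), ev$to)),
    gain = sort(c(genotype, ev$to)),
    loss = sort(multiset_diff(genotype, ev$from)),
    stop("unknown event kind: ", ev$kind))
}

# Successor events from a genotype, in deterministic lexicographic order
# (kind, then alleles).
successor_events <- function(genotype, alleles) {
  evs <- list()
  for (a in sort(unique(genotype))) {
    for (b in setdiff(sort(alleles), a)) {
      evs[[length(evs) + 1L]] <- list(kind = "conversion", from = a, to = b)
    }
  }
  for (b in sort(alleles)) {
    evs[[length(evs) + 1L]] <- list(kind = "gain", from = NA_character_,
                                    to = b)
  }
  if (length(genotype) > 1L) {
    for (a in sort(unique(genotype))) {
      evs[[length(evs) + 1L]] <- list(kind = "loss", from = a,
                                      to = NA_character_)
    }
  }
  evs
}

#' Enumerate all shortest mutation paths between two genotypes
#'
#' Considers sequences of conversion, gain and loss events applied to the
#' t0 genotype multiset, iteratively deepening until one or more sequences
#' reach the outgrowth genotype; all sequences of that minimal length are
#' returned in deterministic order.  Parsimony (minimal event count) defines
#' the accepted paths; ties are exactly the ambiguity cases handled by
#' [extract_consensus_events()].
#'
#' @param t0_genotype,outgrowth_genotype Allele multisets (character
#'   vectors).
#' @param alleles Observed alleles available to conversions and gains.
#' @return List of paths, each a list of events (`kind`, `from`, `to`).
#'   Identical genotypes yield a single empty path.
#' @export
enumerate_shortest_paths <- function(t0_genotype, outgrowth_genotype,
                                     alleles) {
  stopifnot(length(t0_genotype) >= 1, length(outgrowth_genotype) >= 1)
  g0 <- sort(t0_genotype)
  g1 <- sort(outgrowth_genotype)
  if (identical(g0, g1)) return(list(list()))
  alleles <- sort(unique(c(alleles, g0, g1)))
  count_diff <- sum(vapply(alleles, function(a) {
    abs(sum(g0 == a) - sum(g1 == a))
  }, numeric(1)))
  cap <- abs(length(g0) - length(g1)) + count_diff + 2L
  target <- multiset_key(g1)
  for (depth in seq_len(cap)) {
    paths <- dfs_paths(g0, target, alleles, depth)
    if (length(paths)) return(paths)
  }
  stop("no mutation path found within search depth cap (", cap, ")")
}

dfs_paths <- function(genotype, target, alleles, depth) {
  if (depth == 0L) {
    if (multiset_key(genotype) == target) return(list(list()))
    return(list())
  }
  # prune: each event changes cardinality by at most 1
  target_n <- length(strsplit(target, "\r", fixed = TRUE)[[1]])
  if (abs(length(genotype) - target_n) > depth) return(list())
  out <- list()
  for (ev in successor_events(genotype, alleles)) {
    sub <- dfs_paths(apply_event(genotype, ev), target, alleles, depth - 1L)
    for (p in sub) out[[length(out) + 1L]] <- c(list(ev), p)
  }
  out
}

#' Extract certain and ambiguous events from shortest paths
#'
#' Events are compared as multisets.  First, events present in every path
#' (multiset intersection) are reported as certain.  Second, the remaining
#' events are grouped by (kind, starting allele); a group present in every
#' path is reported as one ambiguous event whose target set collects the
#' alternatives (gains group on kind alone and an ambiguous gain is
#' reported with an asterisk target).
#'
#' @param paths Paths from [enumerate_shortest_paths()].
#' @return List with `certain` (list of events) and `ambiguous` (list of
#'   `kind`, `from`, `targets`).
#' @export
extract_consensus_events <- function(paths) {
  stopifnot(length(paths) >= 1)
  keys <- lapply(paths, function(p) vapply(p, event_key, character(1)))
  common <- keys[[1]]
  for (k in keys[-1]) common <- multiset_intersect(common, k)
  certain <- lapply(common, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    list(kind = parts[1], from = parts[2], to = parts[3])
  })
  remaining <- lapply(keys, function(k) multiset_diff(k, common))
  ambiguous <- list()
  group_of <- function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    paste(parts[1], parts[2], sep = "\r")
  }
  groups <- unique(unlist(lapply(remaining, function(k) {
    vapply(k, group_of, character(1))
  })))
  for (g in groups) {
    in_all <- all(vapply(remaining, function(k) {
      any(vapply(k, group_of, character(1)) == g)
    }, logical(1)))
    if (!in_all) next
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    targets <- sort(unique(unlist(lapply(remaining, function(k) {
      members <- k[vapply(k, group_of, character(1)) == g]
      vapply(members, function(m) strsplit(m, "\r", fixed = TRUE)[[1]][3],
             character(1))
    }))))
    targets <- targets[targets != "NA"]
    ambiguous[[length(ambiguous) + 1L]] <-
      list(kind = parts[1],
           from = if (parts[2] == "NA") NA_character_ else parts[2],
           targets = targets)
  }
  list(certain = certain, ambiguous = ambiguous)
}

#' Flag potential allelic conversion (PAC) events
#'
#' A conversion whose target allele already exists in the t0 genotype,
#' with no change in copy number, increases the count of an existing allele
#' and can point to gene conversion or larger rearrangements.  For an
#' ambiguous conversion the flag is `"ambiguous"` when it depends on which
#' member of the ambiguity group applies.
#'
#' @param events An [extract_consensus_events()] result.
#' @param t0_genotype,outgrowth_genotype Allele multisets.
#' @return `"yes"`, `"no"` or `"ambiguous"`.
#' @export
flag_pac <- function(events, t0_genotype, outgrowth_genotype) {
  if (length(t0_genotype) != length(outgrowth_genotype)) return("no")
  flags <- character(0)
  for (ev in events$certain) {
    if (ev$kind == "conversion") {
      flags <- c(flags, if (ev$to %in% t0_genotype) "yes" else "no")
    }
  }
  for (ev in events$ambiguous) {
    if (ev$kind == "conversion") {
      pre <- ev$targets %in% t0_genotype
      flags <- c(flags,
                 if (all(pre)) "yes" else if (any(pre)) "ambiguous" else "no")
    }
  }
  if (any(flags == "yes")) return("yes")
  if (any(flags == "ambiguous")) return("ambiguous")
  "no"
}

#' Format a mutation event as an HGVS-style string
#'
#' Standard substitutions, deletions and insertions of the reference allele
#' follow HGVS genomic (`g.`) conventions.  Events outside HGVS's scope use
#' these extensions: copy-number gain `g.1000gainA`; loss `g.1000lossA`;
#' a CNV with ambiguous allele `g.1000gain*`; a mutation within a
#' non-reference allele is addressed through its flanking positions, e.g.
#' `g.999_1001G>C`; ambiguous alternatives are joined with pipes, e.g.
#' `g.1000A>C|g.1000A>G`.
#'
#' @param event An event (`kind`, `from`, `to`) or ambiguous event
#'   (`kind`, `from`, `targets`).
#' @param chrom Chromosome (unused in the string; kept for interface
#'   symmetry).
#' @param pos 1-based site position (anchor of the reference allele).
#' @param ref_allele The site's reference allele.
#' @return An HGVS-style string.
#' @export
format_hgvs <- function(event, chrom, pos, ref_allele) {
  if (!is.null(event$targets)) {
    if (event$kind %in% c("gain", "loss") && length(event$targets) > 1L) {
      return(paste0("g.", pos, event$kind, "*"))
    }
    alts <- vapply(event$targets, function(t) {
      format_hgvs(list(kind = event$kind, from = event$from, to = t),
                  chrom, pos, ref_allele)
    }, character(1))
    return(paste(alts, collapse = "|"))
  }
  switch(event$kind,
    gain = paste0("g.", pos, "gain", event$to),
    loss = paste0("g.", pos, "loss", event$from),
    conversion = format_conversion_hgvs(event, pos, ref_allele))
}

format_conversion_hgvs <- function(event, pos, ref_allele) {
  from <- event$from; to <- event$to
  if (from != ref_allele) {
    # non-reference source allele: address by flanks around the ref allele
    return(paste0("g.", pos - 1L, "_", pos + nchar(ref_allele), from, ">", to))
  }
  nf <- nchar(from); nt <- nchar(to)
  if (nf == 1L && nt == 1L) {
    return(paste0("g.", pos, from, ">", to))
  }
  if (nf > nt && substr(from, 1L, nt) == to) {
    # left-anchored deletion of the trailing bases
    s <- pos + nt
    e <- pos + nf - 1L
    deleted <- substr(from, nt + 1L, nf)
    return(if (s == e) paste0("g.", s, "del", deleted)
           else paste0("g.", s, "_", e, "del", deleted))
  }
  if (nt > nf && substr(to, 1L, nf) == from) {
    # insertion after the last base of the reference allele
    inserted <- substr(to, nf + 1L, nt)
    return(paste0("g.", pos + nf - 1L, "_", pos + nf, "ins", inserted))
  }
  paste0("g.", pos, from, ">", to)
}

#' Infer and name mutation events between two genotype calls
#'
#' Convenience wrapper: enumerates shortest paths between the clonal
#' genotypes, extracts certain and ambiguous events, flags PACs and builds
#' the HGVS string (pipe-joined over events).  A retained subclonal allele
#' in the outgrowth is appended as a subclonal conversion annotation.
#'
#' @param t0_call,outgrowth_call [call_genotype()] results.
#' @param alleles Site alleles, reference first.
#' @param chrom,pos Site coordinates.
#' @return List with `events` (certain + ambiguous), `hgvs` and `pac`.
#' @export
infer_mutation_events <- function(t0_call, outgrowth_call, alleles, chrom,
                                  pos) {
  paths <- enumerate_shortest_paths(t0_call$clonal, outgrowth_call$clonal,
                                    alleles)
  events <- extract_consensus_events(paths)
  pac <- flag_pac(events, t0_call$clonal, outgrowth_call$clonal)
  hgvs <- c(
    vapply(events$certain, format_hgvs, character(1), chrom = chrom,
           pos = pos, ref_allele = alleles[1]),
    vapply(events$ambiguous, format_hgvs, character(1), chrom = chrom,
           pos = pos, ref_allele = alleles[1])
  )
  if (!is.na(outgrowth_call$fraction)) {
    sub_ev <- list(kind = "conversion", from = outgrowth_call$sub_from,
                   to = outgrowth_call$sub_to)
    hgvs <- c(hgvs, paste0(format_hgvs(sub_ev, chrom, pos, alleles[1]),
                           "(subclonal:", outgrowth_call$fraction, ")"))
  }
  list(events = c(events$certain, events$ambiguous),
       certain = events$certain, ambiguous = events$ambiguous,
       hgvs = paste(hgvs, collapse = ";"), pac = pac)
}
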