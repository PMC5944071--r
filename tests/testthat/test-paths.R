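test_that("identical genotypes yield one empty path; simple cases are unique", {
  p0 <- enumerate_shortest_paths(c("A", "A"), c("A", "A"), c("A", "C"))
  expect_length(p0, 1L)
  expect_length(p0[[1]], 0L)

  p1 <- enumerate_shortest_paths(c("A", "A"), c("A", "C"), c("A", "C"))
  expect_length(p1, 1L)
  expect_equal(p1[[1]][[1]],
               list(kind = "conversion", from = "A", to = "C"))
})

test_that("multi-event inference matches brute-force enumeration and grouping", {
  paths <- enumerate_shortest_paths(c("A", "C"), c("C", "C", "G"),
                                    c("A", "C", "G"))
  expect_true(all(lengths(paths) == 2L))
  want <- brute_force_paths(c("A", "C"), c("C", "C", "G"), c("A", "C", "G"))
  key <- function(p) paste(vapply(p, function(e) {
    paste(e$kind, e$from, e$to)
  }, character(1)), collapse = ";")
  expect_setequal(vapply(paths, key, character(1)),
                  vapply(want, key, character(1)))

  ev <- extract_consensus_events(paths)
  expect_length(ev$certain, 0L)
  kinds <- vapply(ev$ambiguous, `[[`, character(1), "kind")
  expect_setequal(kinds, c("conversion", "gain"))
  conv <- ev$ambiguous[[which(kinds == "conversion")]]
  expect_equal(conv$from, "A")
  expect_equal(conv$targets, c("C", "G"))
  gain <- ev$ambiguous[[which(kinds == "gain")]]
  expect_equal(gain$targets, c("C", "G"))
})

test_that("order-only path differences leave both conversions certain", {
  paths <- enumerate_shortest_paths(c("A", "A"), c("C", "G"),
                                    c("A", "C", "G"))
  expect_length(paths, 2L)  # the two orders
  ev <- extract_consensus_events(paths)
  expect_length(ev$certain, 2L)
  expect_length(ev$ambiguous, 0L)
  tos <- sort(vapply(ev$certain, `[[`, character(1), "to"))
  expect_equal(tos, c("C", "G"))
})

test_that("every returned path applied to t0 reproduces the outgrowth genotype", {
  apply_path <- function(g, path) {
    for (ev in path) {
      if (ev$kind == "conversion") {
        g <- sort(c(g[-match(ev$from, g)], ev$to))
      } else if (ev$kind == "gain") {
        g <- sort(c(g, ev$to))
      } else {
        g <- sort(g[-match(ev$from, g)])
      }
    }
    g
  }
  cases <- list(
    list(c("A", "A"), c("A", "C")),
    list(c("A", "C"), c("C", "C", "G")),
    list(c("A", "A", "A"), c("A", "C")),
    list(c("AA", "AA"), c("A", "AA")),
    list(c("A", "C"), c("G", "T")))
  for (cs in cases) {
    paths <- enumerate_shortest_paths(cs[[1]], cs[[2]],
                                      unique(c(cs[[1]], cs[[2]])))
    for (p in paths) {
      expect_equal(apply_path(sort(cs[[1]]), p), sort(cs[[2]]))
    }
  }
})

test_that("shortest length and path sets equal brute force over genotype pairs", {
  alleles <- c("A", "C", "G")
  genos <- list()
  for (n in 1:3) {
    grid <- expand.grid(rep(list(alleles), n), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      genos[[length(genos) + 1L]] <- sort(as.character(unlist(grid[i, ])))
    }
  }
  genos <- unique(genos)
  key <- function(p) paste(vapply(p, function(e) {
    paste(e$kind, e$from, e$to)
  }, character(1)), collapse = ";")
  with_seed(401, {
    idx <- sample(length(genos)^2, 60)
    for (ij in idx) {
      i <- (ij - 1) %/% length(genos) + 1
      j <- (ij - 1) %% length(genos) + 1
      got <- enumerate_shortest_paths(genos[[i]], genos[[j]], alleles)
      want <- brute_force_paths(genos[[i]], genos[[j]], alleles)
      expect_equal(sort(vapply(got, key, character(1))),
                   sort(vapply(want, key, character(1))),
                   info = paste(paste(genos[[i]], collapse = "|"), "->",
                                paste(genos[[j]], collapse = "|")))
    }
  })
})

test_that("PAC flags pre-existing conversion targets, with ambiguity propagation", {
  ev_yes <- list(certain = list(list(kind = "conversion", from = "A",
                                     to = "C")), ambiguous = list())
  expect_equal(flag_pac(ev_yes, c("A", "C"), c("C", "C")), "yes")
  expect_equal(flag_pac(ev_yes, c("A", "A"), c("A", "C")), "no")
  ev_amb <- list(certain = list(),
                 ambiguous = list(list(kind = "conversion", from = "A",
                                       targets = c("C", "G"))))
  expect_equal(flag_pac(ev_amb, c("A", "C"), c("C", "C")), "ambiguous")
  expect_equal(flag_pac(ev_amb, c("A", "T"), c("C", "T")), "no")
  # copy-number change suppresses the PAC flag
  expect_equal(flag_pac(ev_yes, c("A", "C"), c("C", "C", "C")), "no")
})

test_that("HGVS-style naming covers standard and extended cases", {
  expect_equal(format_hgvs(list(kind = "gain", from = NA, to = "A"),
                           "chr1", 1000, "A"), "g.1000gainA")
  expect_equal(format_hgvs(list(kind = "loss", from = "A", to = NA),
                           "chr1", 1000, "A"), "g.1000lossA")
  expect_equal(format_hgvs(list(kind = "gain", from = NA,
                                targets = c("A", "C")), "chr1", 1000, "A"),
               "g.1000gain*")
  # substitution of the reference allele
  expect_equal(format_hgvs(list(kind = "conversion", from = "A", to = "C"),
                           "chr1", 1000, "A"), "g.1000A>C")
  # mutation within a non-reference allele: flank-addressed
  expect_equal(format_hgvs(list(kind = "conversion", from = "G", to = "C"),
                           "chr1", 1000, "A"), "g.999_1001G>C")
  # ambiguous conversion joined with pipes
  expect_equal(format_hgvs(list(kind = "conversion", from = "A",
                                targets = c("C", "G")), "chr1", 1000, "A"),
               "g.1000A>C|g.1000A>G")
  # left-anchored deletion and insertion within a repeat allele
  expect_equal(format_hgvs(list(kind = "conversion", from = "AAA",
                                to = "AA"), "chr1", 500, "AAA"),
               "g.502delA")
  expect_equal(format_hgvs(list(kind = "conversion", from = "AAAA",
                                to = "AA"), "chr1", 500, "AAAA"),
               "g.502_503delAA")
  expect_equal(format_hgvs(list(kind = "conversion", from = "AA",
                                to = "AAA"), "chr1", 500, "AA"),
               "g.501_502insA")
})
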