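test_that("model enumeration covers all clonal multisets and one-allele subclonal variants", {
  m <- enumerate_genotype_models(c("A", "C"), 2)
  clonal_only <- Filter(function(x) is.na(x$fraction), m)
  expect_length(clonal_only, 3L)  # AA, AC, CC
  keys <- sapply(clonal_only, function(x) paste(x$clonal, collapse = ""))
  expect_setequal(keys, c("AA", "AC", "CC"))
  # subclonal: each clonal has one substitutable allele choice per distinct
  # allele; dedup over (clonal, subclonal genotype, fraction)
  sub <- Filter(function(x) !is.na(x$fraction), m)
  sub_keys <- sapply(sub, function(x) {
    paste(paste(x$clonal, collapse = ""),
          paste(sort(c(x$clonal[-match(x$sub_from, x$clonal)], x$sub_to)),
                collapse = ""), x$fraction)
  })
  expect_equal(anyDuplicated(sub_keys), 0L)
  expect_length(sub, 12L)  # AA->AC, AC->AA, AC->CC, CC->AC, x3 fractions

  one <- enumerate_genotype_models("A", 2)
  expect_length(one, 1L)
  expect_true(is.na(one[[1]]$fraction))

  hap <- enumerate_genotype_models(c("A", "C"), 1)
  expect_length(Filter(function(x) is.na(x$fraction), hap), 2L)
  expect_length(Filter(function(x) !is.na(x$fraction), hap), 6L)
})

test_that("expected frequencies follow the clonal/subclonal mixture formula", {
  e1 <- expected_frequencies(list(clonal = c("A", "A"), fraction = NA_real_))
  expect_equal(unname(e1["A"]), 1)
  e2 <- expected_frequencies(list(clonal = c("A", "A"), sub_from = "A",
                                  sub_to = "C", fraction = 0.25))
  expect_equal(unname(e2[c("A", "C")]), c(0.875, 0.125))
  e3 <- expected_frequencies(list(clonal = c("A", "C"), sub_from = "A",
                                  sub_to = "C", fraction = 0.5))
  expect_equal(unname(e3[c("A", "C")]), c(0.25, 0.75))
  # frequencies always sum to 1
  with_seed(301, for (i in 1:20) {
    al <- sample(c("A", "C", "G", "T"), sample(2:4, 1))
    g <- sort(sample(al, 2, replace = TRUE))
    from <- sample(g, 1)
    to <- sample(setdiff(al, from), 1)
    e <- expected_frequencies(list(clonal = g, sub_from = from, sub_to = to,
                                   fraction = sample(c(0.5, 0.25, 0.125), 1)),
                              al)
    expect_equal(sum(e), 1)
    expect_true(all(e >= 0))
  })
})

test_that("single-unit error correction matches the worked homopolymer example", {
  model <- constant_indel_error_model(0.03, 0.05)
  ctx <- list(unit = "A", unit_length = 1L, ref_allele = "AA",
              ref_tract_length = 2L)
  out <- correct_for_indel_error(c(AA = 1), ctx, model)
  expect_equal(unname(out[c("A", "AA", "AAA")]), c(0.05, 0.92, 0.03))

  # zero rates and missing context are identities
  expect_equal(correct_for_indel_error(c(AA = 1), ctx,
                                       constant_indel_error_model(0, 0)),
               c(AA = 1))
  expect_equal(correct_for_indel_error(c(AA = 1), NULL, model), c(AA = 1))

  # mass conservation over random rate pairs and genotypes
  with_seed(302, for (i in 1:100) {
    m <- constant_indel_error_model(runif(1, 0, 0.2), runif(1, 0, 0.2))
    f <- c(0.5, 0.5)
    names(f) <- c(strrep("A", sample(2:6, 1)), strrep("A", sample(7:9, 1)))
    ctx2 <- list(unit = "A", unit_length = 1L, ref_allele = names(f)[1],
                 ref_tract_length = nchar(names(f)[1]))
    out2 <- correct_for_indel_error(f, ctx2, m)
    expect_equal(sum(out2), 1)
    expect_true(all(out2 >= 0))
  })
})

test_that("flooring replaces zeros with 2/depth and only raises masses", {
  expect_equal(floor_frequencies(c(A = 1, C = 0), 100), c(A = 1, C = 0.02))
  expect_equal(floor_frequencies(c(A = 0.7, C = 0.3), 100),
               c(A = 0.7, C = 0.3))
  expect_equal(unname(floor_frequencies(c(A = 1, C = 0), 40)["C"]), 0.05)
  expect_error(floor_frequencies(c(A = 1), 0), "total_depth")
})

test_that("genotype score is zero at equality and matches direct evaluation", {
  expect_equal(score_genotype(c(A = 0.5, C = 0.5), c(A = 0.5, C = 0.5)), 0)
  s <- score_genotype(c(A = 0.5, C = 0.5), c(A = 0.25, C = 0.75))
  expect_equal(s, abs(log(2)) + abs(log(2 / 3)))
})

test_that("called genotypes equal the exhaustive minimum-score oracle", {
  with_seed(303, for (i in 1:200) {
    n_alleles <- sample(2:3, 1)
    alleles <- sort(sample(c("A", "C", "G", "T"), n_alleles))
    cn <- sample(1:3, 1)
    depth <- sample(30:80, 1)
    freqs <- as.numeric(rmultinom(1, depth, runif(n_alleles)))
    top <- rbinom(n_alleles, freqs, 0.5)
    counts <- cmat(top, freqs - top, alleles)
    call <- call_genotype(counts, alleles, cn, role = "t0")
    want <- brute_force_min_score(counts, alleles, cn)
    expect_equal(call$score, want, tolerance = 1e-10)
  })
})

test_that("score ties break toward the reference (t0) or shared alleles (outgrowth)", {
  # exactly symmetric counts make A|A and C|C tie; reference A wins for t0
  counts <- cmat(c(25, 25), c(25, 25), c("A", "C"))
  t0 <- call_genotype(counts, c("A", "C"), 2, role = "t0")
  # A|C fits 50/50 exactly (score 0); construct a genuine tie instead:
  # single observed allele at two copy numbers is trivial, so use zero-depth
  # alleles: A only observed, models A|A vs others
  counts2 <- cmat(c(30, 0), c(30, 0), c("A", "C"))
  t0b <- call_genotype(counts2, c("A", "C"), 2, role = "t0")
  expect_equal(t0b$clonal, c("A", "A"))

  # t0 tie: equal-score A|A vs C|C at symmetric observed frequencies with
  # only those two models (single shared allele pair); force via equal counts
  # of A and C and copy number 1
  counts3 <- cmat(c(20, 20), c(20, 20), c("A", "C"))
  t1 <- call_genotype(counts3, c("A", "C"), 1, role = "t0")
  expect_equal(t1$clonal, "A")  # reference allele preferred on tie

  out <- call_genotype(counts3, c("A", "C"), 1, role = "outgrowth",
                       t0_call = list(clonal = "C"))
  expect_equal(out$clonal, "C")  # shared-with-t0 preferred on tie

  # clean homozygous site
  t2 <- call_genotype(cmat(c(30, 0), c(30, 0), c("A", "C")), c("A", "C"), 2,
                      role = "t0")
  expect_equal(t2$clonal, c("A", "A"))
  expect_lt(t2$score, 0.1)
  expect_true(is.na(t2$fraction))
})

test_that("subclonal validation applies binomial then strand-bias Sidak tests", {
  bias <- structure(list(mean = 0, sd = 0.3),
                    class = "strand_bias_distribution")
  alleles <- c("A", "C")
  # 12/100 reads of C, clonal A|A: floored expected rate 2/100
  counts <- cmat(c(44, 6), c(44, 6), alleles)
  call <- structure(list(clonal = c("A", "A"), sub_from = "A", sub_to = "C",
                         fraction = 0.25, score = 0.1, depth = 100,
                         reverted = NA_character_), class = "genotype_call")
  n_tests <- 1e7
  v <- validate_subclonal(call, counts, alleles, NULL, NULL, bias, n_tests,
                          role = "outgrowth")
  # oracle: exact binomial against the Sidak threshold
  p <- pbinom(11, 100, 0.02, lower.tail = FALSE)
  alpha <- sidak_alpha(0.01, n_tests)
  if (p <= alpha) {
    expect_false(is.na(v$fraction))
  } else {
    expect_true(is.na(v$fraction))
    expect_equal(v$reverted, "binomial")
  }

  # zero supporting reads always reverts
  call0 <- call
  counts0 <- cmat(c(50, 0), c(50, 0), alleles)
  v0 <- validate_subclonal(call0, counts0, alleles, NULL, NULL, bias, 1e6,
                           role = "outgrowth")
  expect_true(is.na(v0$fraction))
  expect_equal(v0$reverted, "binomial")

  # strong subclonal signal on a single strand reverts for strand bias;
  # in a t0 sample this also suppresses the site
  counts1 <- cmat(c(35, 15), c(50, 0), alleles)
  v1 <- validate_subclonal(call, counts1, alleles, NULL, NULL, bias, 1e6,
                           role = "t0")
  # oracle: gaussian tail of ln(16/1) under N(0, 0.3)
  p_bias <- 2 * pnorm(log(16), 0, 0.3, lower.tail = FALSE)
  if (p_bias < sidak_alpha(0.01, 1e6)) {
    expect_equal(v1$reverted, "strand_bias")
    expect_true(isTRUE(v1$suppress_site))
  }
})
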