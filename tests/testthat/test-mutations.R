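test_that("Sidak correction has the exact closed form and round-trips", {
  expect_equal(sidak_alpha(0.01, 1), 0.01)
  expect_equal(sidak_alpha(0.01, 1e7), 1.00503358e-9, tolerance = 1e-6)
  for (n in c(1, 10, 1e4, 1e7)) {
    a <- sidak_alpha(0.01, n)
    # round trip in log space, where the n-fold power does not amplify
    # representation error of the tiny per-test alpha
    expect_lt(abs(exp(n * log1p(-a)) - 0.99), 1e-12)
  }
  expect_error(sidak_alpha(0, 10))
})

test_that("proportional counts give null statistics; strong shifts give calls", {
  t0 <- cmat(c(25, 1), c(25, 1), c("A", "C"))
  # outgrowth exactly proportional to t0
  out_prop <- cmat(c(25, 1), c(25, 1), c("A", "C"))
  s <- compare_site(t0, out_prop)
  expect_gt(s$p_chi, 0.5)
  expect_true(all(s$alleles$p_top >= 0.5 | s$alleles$p_bottom >= 0.5))
  th <- mutation_thresholds(0.01, 1e6)
  expect_false(decide_mutation(s, th)$call)

  # het appears at 25:25 per strand
  out_het <- cmat(c(25, 25), c(25, 25), c("A", "C"))
  s2 <- compare_site(t0, out_het)
  expect_lt(s2$p_chi, 1e-10)
  c_row <- s2$alleles[s2$alleles$allele == "C", ]
  expect_lt(c_row$p_top, 1e-10)
  expect_lt(c_row$p_bottom, 1e-10)
  expect_gt(c_row$composite, th$composite_threshold)
  d <- decide_mutation(s2, th)
  expect_true(d$call)
  expect_true("C" %in% d$alleles)

  # new allele on one strand only: strand-marginal rule rejects it
  out_ss <- cmat(c(25, 20), c(25, 0), c("A", "C"))
  s3 <- compare_site(t0, out_ss)
  c3 <- s3$alleles[s3$alleles$allele == "C", ]
  expect_lt(c3$p_top, 1e-6)
  expect_gt(c3$p_bottom, 0.5)
  expect_false("C" %in% decide_mutation(s3, th)$alleles)
})

test_that("degenerate sites (single strand or single allele) are skipped", {
  one_strand <- cmat(c(25, 5), c(0, 0), c("A", "C"))
  both <- cmat(c(12, 3), c(13, 2), c("A", "C"))
  expect_null(compare_site(one_strand, both))
  expect_null(compare_site(both, one_strand))
  mono_a <- cmat(c(20, 0), c(25, 0), c("A", "C"))
  expect_null(compare_site(mono_a, mono_a))
  expect_false(is.null(compare_site(both, both)))
})

test_that("the decision rule is the stated conjunction, checked at the boundary", {
  th <- mutation_thresholds(0.01, 1e6)
  mk_stats <- function(p_chi, p_top, p_bottom) {
    comp <- sqrt(log10(p_top)^2 + log10(p_bottom)^2 + log10(p_chi)^2)
    list(p_chi = p_chi,
         alleles = data.frame(allele = "C", p_top = p_top,
                              p_bottom = p_bottom, composite = comp))
  }
  # p_chi failing alone blocks the call
  expect_false(decide_mutation(mk_stats(0.5, 1e-10, 1e-10), th)$call)
  # all three satisfied
  expect_true(decide_mutation(mk_stats(0.05, 1e-8, 1e-8), th)$call)
  # marginal rule: one strand p above 0.1 blocks even with huge composite
  expect_false(decide_mutation(mk_stats(1e-12, 1e-12, 0.2), th)$call)
  # boundary: p values chosen so the composite sits just at the threshold
  p_axis <- 10^(-th$composite_threshold / sqrt(3))
  boundary <- mk_stats(p_axis, p_axis, p_axis)
  direct <- sqrt(3) * (-log10(p_axis)) > th$composite_threshold
  expect_equal(decide_mutation(boundary, th)$call, direct)
  above <- mk_stats(p_axis * 0.5, p_axis * 0.5, p_axis * 0.5)
  expect_true(decide_mutation(above, th)$call)
})

test_that("the decision is monotone in the novel allele's count", {
  th <- mutation_thresholds(0.01, 1e6)
  t0 <- cmat(c(30, 1), c(30, 1), c("A", "C"))
  called <- vapply(0:25, function(k) {
    out <- cmat(c(30 - 0, k), c(30, k), c("A", "C"))
    decide_mutation(compare_site(t0, out), th)$call
  }, logical(1))
  # once called, adding supporting reads never un-calls
  expect_true(all(diff(called) >= 0))
})

test_that("site filters apply in order with the stated statuses", {
  alleles <- c("A", "C")
  mut_site <- function(pos) {
    make_site(pos, alleles,
              anc = cmat(c(25, 0), c(25, 0), alleles),
              des = cmat(c(13, 12), c(12, 13), alleles))
  }
  low <- make_site(50, alleles,
                   anc = cmat(c(3, 1), c(4, 2), alleles),
                   des = cmat(c(3, 1), c(2, 2), alleles))
  single <- make_site(60, alleles,
                      anc = cmat(c(25, 5), c(0, 0), alleles),
                      des = cmat(c(13, 12), c(12, 13), alleles))
  sites <- list(mut_site(10), mut_site(30), low, single, mut_site(100))
  regions <- list(anc = data.frame(chrom = "chr1", start = 25L, end = 35L),
                  des = NULL)
  excl <- data.frame(chrom = "chr1", start = 95L, end = 110L)
  res <- call_mutations(sites, "anc", "des",
                        ploidy = list(anc = 2L, des = 2L), n_tests = 1e6,
                        abnormal_regions = regions, exclusions = excl)
  expect_equal(res$site_status$filter_status,
               c("pass", "abnormal_depth", "low_depth",
                 "single_strand_single_allele", "excluded_region"))
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$filter_status, "pass")
  expect_equal(res$records$pos, 10L)
  expect_equal(res$records$outgrowth_genotype, "A|C")
  expect_equal(res$records$hgvs, "g.10A>C")
})

test_that("local copy number overrides change genotype cardinality", {
  alleles <- c("A", "C")
  site <- make_site(10, alleles,
                    anc = cmat(c(25, 0), c(25, 0), alleles),
                    des = cmat(c(19, 6), c(18, 7), alleles))
  cn <- data.frame(chrom = "chr1", start = 0L, end = 100L, copy_number = 4L)
  res <- call_mutations(list(site), "anc", "des",
                        ploidy = list(anc = 2L, des = 2L), n_tests = 1e6,
                        copy_number_maps = list(anc = cn, des = cn))
  expect_equal(nrow(res$records), 1L)
  expect_equal(lengths(strsplit(res$records$outgrowth_genotype, "|",
                                fixed = TRUE)), 4L)
})
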