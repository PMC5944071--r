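---
title: "Calling accumulated mutations from matched ancestor/descendant samples"
author: "macall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling accumulated mutations from matched ancestor/descendant samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macall)
```

## The problem

In a mutation accumulation experiment a founder sample (t0) is propagated
through repeated single-cell bottlenecks, and descendant samples
(outgrowths) are sequenced alongside it.  Every allele that differs between
an outgrowth and t0 — rather than between either sample and the reference —
is a candidate accumulated mutation.  Because ancestor and descendants are
essentially isogenic, both are subject to the same locus-specific mapping
and sequencing artifacts, which is what makes very low false positive rates
achievable: the ancestor acts as a matched control at every position.

Indels in simple repeats are the hard case.  Polymerase slippage during
library PCR creates reads one repeat unit longer or shorter than the
template at rates that rise steeply with tract length, so a naive caller
either drowns in slippage artifacts or throws away true repeat indels.
`macall` addresses this with per-sample empirical error models and an
error-aware genotype scoring scheme, combined with a strand-aware
statistical comparison of ancestor and descendant read counts.

`macall` deliberately starts downstream of alignment: its input contract is
a table of strand-specific read counts per allele per sample at candidate
sites (as produced by a local-reassembly variant caller), per-sample depth
tracks in bedGraph format, and a reference FASTA.  Converting a particular
caller's output into the counts table is a documented extension point, not
part of the package.

## Per-sample models

**Depth.**  Per-position depths, divided by the local copy number (sample
ploidy, or a user-supplied per-interval copy-number map), are summarised by
a Gaussian fit to their integer-binned frequency histogram
(`fit_depth_distribution()`).  A least-squares curve fit is used rather
than moments because repetitive regions contribute a heavy right tail that
would inflate a moment estimate of the spread.  Windowed mean depths (25 bp
centered windows, truncated at chromosome edges) are then compared against
this Gaussian; positions with two-tailed p below 1e-4, on the same side of
the mean and within 1000 bp of each other, are merged into abnormal-depth
regions (`detect_abnormal_regions()`) that are excluded from calling.  All
three constants are user-tunable; the defaults suit ~50x genomes.

**Chromosome-end bias.**  Depth is often systematically inflated toward
chromosome ends.  The expected depth relative to the genomic mean is
modelled as a complementary log-normal CDF plus a linear term in the
distance `x` to the nearest end:

$$\mathrm{factor}(x) = \mathrm{scalar}\,\Big(1 - \big[\tfrac12 +
\tfrac12\,\mathrm{erf}\big(\tfrac{\ln x - \mu}{\sqrt2\,\sigma}\big)\big]\Big)
+ \mathrm{intercept} + \mathrm{slope}\,x$$

fitted by non-linear least squares to 500-bp-bin medians of the
depth-to-mean ratio, after excluding ratios above 4 or below 0.25
(`fit_depth_correction()`).  `correct_depths()` divides each position by
its factor; a flat ratio profile (no end bias) is reduced to the linear
part, since the log-normal component is then unidentifiable.  Note the
ratio normalisation: if the biased ends occupy a non-trivial fraction of
the genome, the global mean itself absorbs part of the bias and the fitted
intercept sits below 1 — the correction is still self-consistent.

**Strand bias.**  Reads from mismapping-prone loci tend to pile onto one
strand.  Per position, `ln((top + 1) / (bottom + 1))` (one pseudo-count per
strand) is summarised by a Gaussian histogram fit
(`fit_strand_bias_distribution()`); `strand_bias_p_value()` returns
two-tailed `2 min(Φ(z), 1 − Φ(z))` against that distribution.

**Indel error.**  For each sample, reads that fully traverse an annotated
repeat tract are counted along with traversing reads containing an indel
(`aggregate_error_rates()`), pooled per event type (insertion/deletion),
unit length (1-4 nt) and total tract length in bp.  Rates from strata with
fewer than 10 distinct loci are dropped, and the remainder are fit to a
logistic in tract length `x`:

$$\mathrm{error}(x) = M + \frac{L}{1 + e^{-k (x - x_0)}}$$

per event and unit length (`fit_error_function()`).  Initialisation is
`M = min`, `L = max − min`, `x0 = median length`, `k = 1`, with bounds
`M, L ≥ 0`, `k ∈ (0, 10]`, `x0` within 5 bp of the fitted range.
Predictions are clamped to [0, 0.5] so a corrected frequency can never
exceed its source allele's mass under extrapolation.  When a stratum cannot
be fit, its empirical rate is used; unseen strata fall back to 0.
Traversing coverage must be supplied explicitly (the depth track includes
partially overlapping, uninformative reads and would understate error
rates).

## Repeat annotation

`find_repeats()` lists every maximal simple repeat with unit length 1-4 and
total length ≥ 4 bp, eliminating units that are concatenations of shorter
units and tracts wholly contained in a tract of the same unit or a circular
permutation of it.  Tract length is measured in bp and may include a
partial trailing unit (a 4-bp span with period 3 qualifies); bp length is
the axis the error model uses.  `sample_repeats()` draws a seeded uniform
subsample for large genomes.

## Genotype calling

At each candidate site, all genotype models are enumerated
(`enumerate_genotype_models()`): every multiset of observed alleles of
cardinality equal to the local copy number, alone or paired with a
subclonal genotype differing in exactly one allele at fraction 0.500,
0.250 or 0.125 — a mutation in the first, second or third division after
the final bottleneck.  Expected allelic frequencies are the
clonal/subclonal mixture; in a repeat context, single-unit slippage moves
`rate_del` and `rate_ins` of each genotype allele's mass to its one-unit
neighbours (`correct_for_indel_error()`).  For a homozygous diploid `AA|AA`
with insertion rate 0.03 and deletion rate 0.05 this yields

```{r worked-example}
correct_for_indel_error(
  c(AA = 1),
  list(unit = "A", unit_length = 1, ref_allele = "AA", ref_tract_length = 2),
  constant_indel_error_model(0.03, 0.05))
```

Zero frequencies are floored at `2 / depth` — one pseudo-count per strand
(`floor_frequencies()`), with no renormalisation (renormalising would
perturb ties).  Each model is scored as

$$\mathrm{score} = \sum_i \left|\ln(o_i / e_i)\right|$$

over the site's reported alleles, observed frequencies floored the same
way, and the minimum-score model is called (`call_genotype()`).  Error
mass moved to an allele the caller never reported depletes its source but
is not itself scored: an allele with zero observed reads carries no
evidence, and the ratio of its floored observed frequency to a tiny
corrected expectation would contribute a large penalty that is pure
artifact (in testing it let homozygous models tie true heterozygotes at
repeat indel sites).  Score ties go to the genotype with the most
reference alleles (t0) or the most alleles shared with the t0 call
(outgrowths), then to the deterministic enumeration order.

A called subclonal component must then survive two tests
(`validate_subclonal()`): an upper-tail binomial test of the subclonal
allele's pooled count against its floored expectation under the clonal-only
model, at the Šidák per-test threshold (below); and the strand-bias test of
its per-strand counts.  Either failure reverts the call to clonal; a
strand-bias failure in the t0 sample suppresses mutation reporting at that
position entirely, since the control itself is then suspect.

## Identifying mutations

Sites are compared between t0 and each outgrowth (`compare_site()`) with
three statistics:

* a chi-square goodness-of-fit over all allele-by-strand cells, expected
  counts proportional to the t0 cells (one pseudo-count per cell, df =
  cells − 1), giving `p_chi`;
* per allele and per strand, an upper-tail binomial p-value of the
  outgrowth count given the t0 allele fraction on the same strand (floored
  by a pseudo-count where the t0 count is zero), giving `p_top` and
  `p_bottom`.

The composite score per allele is the Euclidean norm
$\sqrt{(\log_{10} p_{top})^2 + (\log_{10} p_{bottom})^2 +
(\log_{10} p_{chi})^2}$ — the distance from certainty that nothing
happened.  With family-wise error rate `fwer` (default 0.01) over
`n_tests` queryable positions, the Šidák per-test threshold is
$\alpha = 1 - (1 - \mathrm{fwer})^{1/n}$ and a site is putative when
`p_chi < 0.1` and some allele has composite score above
$-\log_{10}\alpha$ with both strand p-values below 0.1
(`decide_mutation()`).  The composite threshold is the single-axis bound
$-\log_{10}\alpha$, not its $\sqrt3$ multiple — the conservative reading of
a scalar threshold applied to a vector magnitude.  Requiring both strands
separately is what rejects the classic one-strand mismapping artifact,
which can carry an arbitrarily extreme pooled p-value.

Filters are applied in order (`call_mutations()`): user exclusion regions;
abnormal-depth regions in either sample; depth below 20 in either sample;
degenerate coverage (all of a sample's reads on one strand, or only one
allele observed overall); the statistical thresholds; and the
t0-subclonal-bias suppression.  A site that passes statistically but whose
clonal genotypes do not differ (and with no retained subclonal component)
is not reported.

## Mutation identity

The t0 and outgrowth clonal genotypes are connected by sequences of three
event kinds — conversion of one allele copy, gain of a copy (any observed
allele), loss of a copy — and every minimal-length event sequence is
enumerated (`enumerate_shortest_paths()`, iterative deepening with a
cardinality pruning bound).  Events present in every shortest path
(multiset intersection) are reported as certain; remaining events of the
same kind and starting allele present in every path are merged into one
ambiguous event with a target set (`extract_consensus_events()`).
Conversions whose target already exists in t0 without a copy-number change
are flagged as potential allelic conversions (PACs), with an `ambiguous`
flag when this depends on the ambiguity member (`flag_pac()`).  Names
follow HGVS genomic conventions where they apply, with extensions:
`g.1000gainA`, `g.1000lossA`, `g.1000gain*` (ambiguous CNV allele),
flank-addressed mutations within non-reference alleles
(`g.999_1001G>C`), and pipe-joined ambiguous alternatives
(`g.1000A>C|g.1000A>G`).

## Rates, false negatives, and homopolymer simulation

`mutation_rate()` computes rates per bp per generation,
`N / (N_{bp} \cdot gen_{tot})`, with `N_bp` replaced by the global ploidy
for whole-genome rates.  `false_negative_rate()` implements the binomial
model `B(L; D, p)` for legacy hard-cutoff pipelines: with read length `R`
and tract length `L`, a fraction `p = (R − 2(L + δL)) / (R − (L + δL))` of
reads traverse the tract, and the probability that at most `L` of
`round(D·C)` sampled reads are informative bounds the false negative rate;
rates are corrected by `1/(1 − B)`.  `δL` defaults to 1 (the single-base
case) and is configurable, as the length inflation's exact convention is a
modelling choice.  `simulate_indel_accumulation()` evolves each
homopolymer by ±1 bp per generation at per-length insertion/deletion rates
(re-indexed each generation, clamped to the 7-18 table) and reports the
mean and central 95% envelope of multi-base deletion counts (net loss
≥ 2 bp) per starting length — the comparison interface for asking whether
observed multi-base deletion rates exceed what sequential single-base
events explain.

## The synthetic-data generator

`generate_reference()`, `plant_mutations()` and `generate_pair()` produce
fully specified datasets with known truth, and are the package's test
substrate.  The defaults describe the study conditions: diploid samples at
Gaussian depth 50 ± 7; locus-level strand bias with ln-ratio sd 0.2, drawn
once per site and shared by both samples (bias is a property of the local
mapping context, which isogenic samples share) with binomial read sampling
on top; slippage errors at logistic rates (`M = 0.001, L = 0.15, k = 0.9,
x0 = 10` for deletions in homopolymers, half that amplitude for
insertions), with the take-off length scaling with unit length so that
slippage tracks the number of repeated units — a 2.5-unit tetranucleotide
tract does not slip like a 10-bp homopolymer; substitution noise at 0.002
per read; 60% of reads traversing a repeat.  Candidate sites are planted
mutation positions plus any repeat tract or noise site with at least 3
supporting reads across the pair, emulating the ~2 candidate sites/kbp
that sensitive local-reassembly callers produce on yeast-sized genomes.
An `expected` mode replaces all sampling with rounded expectations for
exact unit tests.

What the generator does not emulate: alignment-induced correlated errors
across neighbouring sites, reference bias, GC-dependent coverage,
multi-unit slippage events, or contamination.  Passing tests therefore
demonstrate the statistical engine's behaviour under its own model
assumptions — calibration and sensitivity on real data additionally depend
on the upstream aligner/caller whose output feeds the counts table.

## Problem sizes and numerical choices

The package's end-to-end checks run on 1-Mbp genomes at 50x: 50
no-mutation replicates for family-wise error control (no replicate may
produce a call in more than 10% of runs), and five replicates with ~200
planted clonal substitutions and 50 single-unit repeat indels (tracts
≤ 10 bp) for sensitivity, chosen to give minute-scale runtimes on one CPU
while leaving thousands of null candidate sites per replicate.  Genotype
and path inference are verified against brute-force enumeration oracles;
the analytic identities (Šidák round trip, binomial false-negative sum,
sequential-deletion probability) are checked to stated precision.

Numerical notes: Šidák thresholds are computed as
`-expm1(log1p(-fwer)/n)` to avoid cancellation; score ties are compared at
1e-9 tolerance; chi-square expected counts are never zero thanks to cell
pseudo-counts; histograms use unit bins for integer depths; the logistic
and depth-correction fits use Levenberg-Marquardt with explicit bounds and
data-driven starts, and degenerate inputs (flat rate tables, flat ratio
profiles) short-circuit to their identifiable sub-models rather than
failing.

## Known limitations

* Subclonal fractions are fixed at {0.5, 0.25, 0.125} at every ploidy; no
  mixture of more than two subpopulations, and no tumor-purity modelling —
  rare-variant detection in heterogeneous samples is out of scope.
* The indel error model covers annotated simple repeats only (unit 1-4);
  errors outside repeats are represented only through the statistical
  comparison itself.
* Copy-number variation must be supplied; the package detects abnormal
  depth but does not call CNVs.
* PAC flags are per site; clustering PACs into candidate gene-conversion
  tracts is left to downstream analysis.
* One t0 per analysis; every outgrowth is compared only against it.
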