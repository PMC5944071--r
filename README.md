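# macall

Mutation calling for mutation accumulation experiments.

In a mutation accumulation experiment a founder sample (**t0**) is grown
through repeated single-cell bottlenecks and one or more descendant
(**outgrowth**) samples are sequenced alongside it.  Mutations are alleles
that differ between outgrowth and t0 — not between either sample and the
reference — so the ancestor serves as a matched control at every genomic
position, which is what makes the very low false positive rates required
for mutation *rate* estimation achievable.  The hard case is insertions and
deletions in simple repeats, where PCR slippage during library preparation
creates artifact reads one repeat unit longer or shorter than the template
at rates that rise steeply with tract length.

`macall` is the statistical engine for this design.  It consumes a
strand-specific allele-count table at candidate sites (the contract a
local-reassembly variant caller fulfils), per-sample depth tracks
(bedGraph), and a reference FASTA, and provides:

* per-sample models of depth (Gaussian on per-copy depth), strand bias
  (Gaussian on ln top/bottom ratios), chromosome-end coverage bias
  (log-normal CDF + linear factor, with depth correction), and PCR
  slippage indel error in repeats (logistic rate vs tract length,
  `error(x) = M + L / (1 + exp(-k (x - x0))`, per event type and unit
  length 1–4);
* genotype calling by minimum score `sum |ln(o_i / e_i)|` over all
  enumerated clonal and clonal+subclonal genotype models (subclonal
  fractions 0.5 / 0.25 / 0.125), with slippage-corrected expected
  frequencies and `2/depth` pseudo-count floors, plus binomial and
  strand-bias validation of subclonal calls;
* mutation identification by a chi-square test over allele-by-strand cells
  plus per-strand binomial tests against the t0 allele fractions, combined
  into a composite score `sqrt(sum of squared -log10 p)` thresholded at
  the Šidák per-test level `1 - (1 - FWER)^(1/n)` over queryable genome
  positions (FWER default 0.01);
* parsimonious mutation-path inference between the called genotypes
  (conversion / gain / loss events; all shortest paths; consensus events
  certain, grouped alternatives ambiguous; potential allelic conversion
  flags) with HGVS-style naming, written to TSV and VCF 4.2;
* mutation-rate utilities, a binomial false-negative model
  `B(L; D, p)` for indels in long tracts, and a Monte Carlo simulator of
  multi-base deletion accumulation in homopolymers;
* a fully seeded synthetic-data generator (reference with planted repeats,
  planted clonal/subclonal mutations, depth and bias noise, slippage
  errors, traversing-coverage observations) so the whole engine is
  testable without external data.

See `vignettes/mutation-accumulation-calling.Rmd` for the models,
parameter meanings, defaults and design choices.

## Worked example

Simulate a 100-kb diploid pair with eight planted mutations, write it to
disk in the standard formats, and run the full pipeline:

```r
library(macall)

spec <- data.frame(unit = "A", tract_length = 6:10, count = 6)
ref <- generate_reference(seed = 7, length = 100000, repeat_spec = spec)
repeats <- find_repeats(ref$seq)
mutations <- plant_mutations(ref, repeats, n_substitutions = 5,
                             n_indels = 3, seed = 8)
pair <- generate_pair(ref, mutations, synthetic_params(), seed = 9,
                      repeats = repeats)

dir <- "demo"
sheet <- write_dataset(pair, ref, dir)
cfg <- pipeline_config(sheet, file.path(dir, "reference.fa"),
                       file.path(dir, "out"))
res <- run_pipeline(cfg)
res$records[, c("chrom", "pos", "ref", "alt", "hgvs", "pac", "p_chi",
                "max_composite")]
```

```
  chrom   pos     ref        alt                hgvs pac        p_chi max_composite
1  chr1 28399       T          G          g.28399T>G  no 1.434637e-46      47.72623
2  chr1 63282       G          C          g.63282G>C  no 6.706420e-89      89.59115
3  chr1 69498  TTTTTT      TTTTT         g.69503delT  no 3.575308e-58      59.66287
4  chr1 73524 GATGATG GATGATGGAT g.73530_73531insGAT  no 2.617960e-51      52.38749
5  chr1 83637       C          T          g.83637C>T  no 5.604508e-31      31.65843
6  chr1 88471       C          G          g.88471C>G  no 2.685949e-50      51.36733
7  chr1 88984 TCGTCGT       TCGT g.88988_88990delCGT  no 9.482384e-59      59.74202
8  chr1 96193       T          A          g.96193T>A  no 4.739105e-62      63.59003
```

All eight planted events (five substitutions, a single-base deletion in a
T homopolymer, and single-unit insertion/deletion in trinucleotide
repeats) are recovered, each with its HGVS-style name.  `p_chi` is the
chi-square p-value comparing outgrowth to t0 counts; `max_composite` is
the largest per-allele composite score, to be read against the Šidák
threshold (here `-log10(alpha) ≈ 7`); `pac` flags potential allelic
conversions.  The output directory also receives the VCF, per-sample
abnormal-region BEDs, and plain-text model parameter files.

A thin command-line interface over the same functions is installed at
`inst/cli/macall.R` (`Rscript macall.R run-pipeline --samples samples.tsv
--reference ref.fa --out-dir out`, plus subcommands for each stage:
`create-repeat-file`, `fit-depth`, `detect-regions`,
`fit-depth-correction`, `correct-depths`, `plot-allelic-fraction`,
`simulate-dataset`, `rates`, `simulate-indels`).

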