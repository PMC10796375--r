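---
title: "Methods: weighted 6mer seed viability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted 6mer seed viability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmer)
```

## The model

Short RNAs loaded into the RNA-induced silencing complex (RISC) silence
their targets through the 6mer seed, nucleotides 2-7 of the 5'→3' guide
strand. Because G-rich seeds complement C-rich seed matches in the 3'UTRs
of survival genes, seed composition carries a toxicity signal: for each of
the 4096 possible 6mer seeds there is a measured percent viability of
cells forced to load that seed into the RISC, averaged over three cell
lines per species (human or mouse). Values above 100% are legal — some
seeds mildly enhance growth.

`sixmer` treats that per-seed viability as a lookup and asks a
population-level question: *is the read-count-weighted distribution of
seed viabilities of a set of RISC-bound small RNAs shifted toward the
toxic (low-viability) end in one condition relative to another?* The unit
of every statistic is not the read sequence but the **expanded viability
multiset**: each sequence contributes `round(weight / divisor)` copies of
its seed's viability, where the weight is a normalized read count (total
mode) or the absolute delta read count (differential mode). Medians, box
statistics, Kruskal-Wallis comparisons, 1%-binned abundance curves and
position-wise seed composition matrices are all computed on that
expansion, so abundant sequences dominate exactly in proportion to their
RISC occupancy.

## Pipeline stages and their contracts

1. **Preprocess** (`fastq_to_counts`): per-sample FASTQ → trimmed reads →
   a sequence-by-sample integer count table. Adapter trimming is exact
   substring matching — leftmost full-adapter hit, or a terminal partial
   hit of at least `min_overlap` (default 4) nucleotides — with no error
   tolerance. Untrimmable reads and inserts under 7 nt (too short to
   carry a seed) are dropped and counted. Quality scores are ignored:
   the analysis is purely count-based. Rows with total count below
   `min_total` (default 6, applied to the row total across samples) are
   removed as rare reads; the threshold is a configuration value and is
   recorded in the run manifest.
2. **Annotate** (`annotate_table`): each sequence is matched against
   three reference sets in fixed priority order — artificial spike/decoy
   sequences, mature miRNAs, then an "RNAworld" catch-all of other small
   RNAs (tRNA/rRNA fragments and the like). A read matches a set when it
   occurs as an exact substring of any reference sequence; ties within a
   set resolve to the first reference in file order. Artificial matches
   are removed; everything else is retained — including unannotated
   reads, because the analysis is deliberately gene-agnostic and only
   needs the seed. Exact containment was chosen over alignment with
   mismatch tolerance: it is deterministic, dependency-free and
   testable, at the cost of missing near-matches; that divergence is
   intentional and documented here.
3. **Normalize** (`normalize_counts`): every sample column is scaled to
   exactly 1,000,000 reads; all-zero columns are left at zero with a
   warning rather than producing NaNs.
4. **Differential selection** (`differential`): per row, a two-sided
   equal-variance Student's t-test on normalized counts between the two
   groups; rows with p below `alpha` (default 0.05) are kept with their
   delta read count (perturbed mean − control mean). No multiple-testing
   correction is applied — the selection rule is the plain per-row
   p < 0.05 filter, stated prominently rather than silently "improved";
   the test name and alpha are recorded in the output attributes and the
   manifest. Rows identically constant in both groups have an undefined
   t statistic and are skipped (not assigned p = 1); rows with zero
   pooled variance but differing means are kept with p = 0. The test is
   isolated behind this one function so a rank or unequal-variance test
   could be substituted without touching the rest of the pipeline.
5. **Weighted statistics** (`expand_viability`, `box_stats`,
   `compare_groups`, `binned_curve`, `seed_composition`): see below.

A second entry mode, `run_mirna_list`, starts from a published list of
miRNA names with signed expression values, resolves each name to its
mature sequence, and runs the same weighted statistics per direction
(up/down) — useful for reanalyzing differential miRNA tables when raw
reads are unavailable.

## Numerical choices

* **Expansion rounding.** Copies are `floor(weight / divisor + 0.5)` —
  round half away from zero. Rounding to nearest preserves totals better
  than flooring; rows that round to zero copies are dropped and their
  number reported, and `divisor = 1` is available when exactness matters
  (the miRNA-list mode defaults to it). The default divisor of 1000 keeps
  multiset sizes near depth/1000 per sample, which makes the rank
  statistics cheap without visibly moving the quantiles.
* **Quantiles.** Median and hinges use linear interpolation between
  order statistics (R's type 7, the common plotting default). Hinge
  values depend on this convention, so it is recorded in the pipeline
  configuration and manifest.
* **Whiskers.** Whiskers extend to the most extreme data point no
  further than 1.5 × IQR beyond the hinges; points beyond are outliers.
* **Group comparison.** The group test is the Kruskal-Wallis rank-sum
  test with tie correction and chi-square p-value (`stats::kruskal.test`).
  The phrase "Kruskal-Wallis median test" occasionally seen for this kind
  of comparison is ambiguous — it could denote Mood's median test — and
  the rank-sum reading is the conventional one adopted here; the function
  takes plain numeric vectors, so a different test is a one-line swap.
  When all values are identical across groups no effect is possible and
  the convention H = 0, p = 1 is returned with a warning.
* **Binning.** Viability bins are left-closed right-open, width 1% by
  default, anchored at 0 and extending past 100% when growth-enhancing
  seeds occur. Rows are first collapsed on (seed, RNA type) so that the
  curve counts seed-level abundance, then binned; bin totals conserve the
  collapsed total weight exactly.
* **Composition matrices.** Computed from the integer copy numbers
  without materializing the expansion, but tested to be identical to the
  literal expand-and-tally result.

## The synthetic data generator

No sequencing data ships with the package; all validation runs on
synthetic inputs whose ground truth is known.

* `gen_viability_table` emulates the *structure* of the measured seed
  screen, not its values: per cell line, viability is a deterministic
  base minus noise, where the base decreases linearly with a G/C-weighted
  content score of the seed (G weighted 1, C weighted 0.45, scaled so the
  all-G seed's base is ~20% and the all-A seed's ~112%), plus Gaussian
  noise (SD 8 percentage points per cell line) clipped at 0. This encodes
  the one qualitative fact the statistics depend on — G-rich seeds are
  toxic, A/U-rich seeds are not — while remaining obviously synthetic.
* `gen_counts` draws unique 18-24 nt sequences embedding uniformly
  sampled seeds at positions 2-7, assigns RNA types at the configured
  fractions (defaults 60% miRNA, 20% RNAworld, 5% artificial, remainder
  unannotated), gives rows log-normal baseline abundances
  (sdlog = 1.5, a heavy tail), and tilts the perturbed group's means by
  `exp(shift * 2.5 * (100 - viability)/100)` before renormalizing both
  groups to the target depth. Counts are Poisson around the per-group
  means. `shift = 0` makes the two groups exchangeable; `shift > 0`
  lowers the perturbed group's expected weighted median viability, the
  synthetic analogue of a shift of RISC-bound sRNAs toward toxic seeds.
* Poisson rather than negative-binomial counts is a deliberate
  simplification: the differential stage is a t-test on normalized
  values, so overdispersion realism is not needed to validate the
  pipeline's contracts — but it does mean the generator understates the
  biological variability of real Ago pulldown libraries.
* `gen_references` and `gen_fastq` close the loop: references cover the
  planted rows exactly (so annotation removal can be checked against
  ground truth), and FASTQ emission followed by preprocessing reproduces
  the generating count table exactly for tables that pass the rare-read
  filter.

Default study conditions are 3 samples per group (a typical replicate
count for Ago pulldown experiments), 10^5–10^6 expected reads per sample
and a few hundred unique sequences; validation suites run the null
calibration at 2000 rows and the shift-recovery experiment at 100
replicates of 300 rows — sizes at which the binomial error of the checked
rates is small relative to their tolerance bands.

What passing these tests shows: the bookkeeping (conservation,
determinism, oracle equality), the calibration of the selection stage
under its own model, and the pipeline's ability to recover a planted
viability shift and its G-content signature. What they do not show:
robustness to overdispersion, adapter errors, isomiR end-heterogeneity or
cross-mapping — all real-data phenomena the generator does not emulate.

## Known limitations

* Reference matching is exact; a single sequencing error sends a read to
  `unknown` (retained, but unnamed) or past an artificial decoy.
* The per-row t-test assumes approximate normality of normalized counts;
  for very low counts it is conservative. The uncorrected p < alpha rule
  selects a set of reads whose size grows with table size under the null
  (by design — it mirrors a delta-read-count selection, not a discovery
  procedure).
* Species averages are unweighted means of the three cell lines; no
  per-cell-line analysis is exposed.
* Curves are emitted as raw per-bin weights; smoothing is a presentation
  concern and is left to the caller.

## Session info

```{r}
sessionInfo()
```
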