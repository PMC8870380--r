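---
title: "Back-tracking somatic variants through serial myeloma precursor samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-tracking somatic variants through serial myeloma precursor samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmbacktrack)
```

## The problem

Multiple myeloma (MM) is consistently preceded by asymptomatic precursor
conditions — monoclonal gammopathy of undetermined significance (MGUS) and
smoldering multiple myeloma (SMM). When serial bone-marrow samples exist for
a patient who eventually progressed, a natural question is *when* the mutant
clone that dominates the MM sample first became detectable. The catch is that
precursor samples are unsorted bone-marrow smears with a low fraction of
aberrant plasma cells, so the variant of interest may sit at a fraction of a
percent — the same order of magnitude as sequencing error.

`mmbacktrack` implements the analysis layer for this design:

1. **Filter** the variants called at the MM timepoint down to the tracked
   set.
2. **Back-track** each tracked variant through the patient's earlier samples,
   judging presence against an empirical background-noise null built from
   unrelated samples.
3. **Re-test** negatives after (simulated or real) deep resequencing.
4. **Assemble** per-variant trajectories, classify patients and summarize
   the cohort.

A simulator generates the entire study structure so every stage is testable
end-to-end without any sequencing data.

## The significance rule

For a candidate variant in a candidate sample, let $f = a/(a+r)$ be its
allele frequency from alt ($a$) and ref ($r$) read counts. The same position
is looked up in $n = 10$ samples drawn (seeded, without replacement) from
*other* patients, giving background frequencies $f_1, \dots, f_n$ with mean
$\bar f$ and sample standard deviation $s$ (the $n-1$ denominator; a
population-SD option exists). The variant is **significantly present** when

$$ f > \bar f + 3s \quad\text{and}\quad a \ge a_{\min}, $$

with strict inequality at the threshold. Positions with no reads give
`no_coverage`; background samples with coverage but zero alt reads
contribute frequency 0; zero-depth samples are ineligible for the panel.

The read-support guard $a_{\min}$ (default 3) replaces the manual
inspection of alignments that such analyses traditionally use to discard
duplicates and artifacts: without it, a noise-free background panel
($\bar f = s = 0$) would declare a single stray read significant. Three
supporting reads is the smallest count that cannot be produced by one
duplicated error read plus its pair; it is deliberately permissive and
configurable.

Samples of the tested patient are excluded from the panel entirely — not
just the tested sample — because a truly early clone would otherwise
contaminate its own null. The panel is drawn per variant with a seed derived
from the variant key, so results do not depend on the order in which
variants are processed.

### Properties the tests pin down

* the threshold equals a naive mean-plus-3-SD recomputation to within
  1e-12 relative error;
* the decision is monotone in alt support at fixed depth, and never flips
  off as depth grows at a fixed frequency;
* on error-only positions (mean error $10^{-3}$, depth 636, 10-sample
  panel, $a_{\min}=3$) fewer than 5% of replicates are called significant;
* at a true VAF of 0.004 the deep regime (3410×) detects at least as often
  as the standard regime (636×) — in practice roughly 60–65% vs 45–50%.

## The filter cascade

MM-phase calls enter tracking only if **all** of these hold (defaults in
parentheses, every one configurable via `filter_config()`):

| gate | rule |
|---|---|
| coverage | total depth strictly `>` 30 reads |
| VAF | `>=` 1% |
| consequence | missense, stop-gain, frameshift or splice-site |
| classification | pathogenic, likely pathogenic or VUS |
| panel | gene on the bundled 81-gene myeloma panel |

Coverage is read as strictly greater than 30 and VAF as at-or-above 1%,
following the usual phrasing of such cascades ("higher than 30", "1% or
higher"); both sit on exact boundaries in the tests. The threshold is
applied to total depth — whether a caller-specific filtered depth was ever
intended is unknowable from the outside, and total depth is the
reproducible choice. Classifications are consumed from input annotations
(they come from an external guideline-based review); records without one
become `unclassified` and are dropped unless the configuration says
otherwise. Multi-allelic records are rejected rather than silently split:
one variant, one trajectory.

Variant representations are normalized (`normalize_variant()`) by
parsimony-trimming and left-alignment through the reference context, so that
the same indel always produces the same key. The implementation is checked
against an exhaustive shift-and-trim enumeration oracle on random 30-bp
contexts.

A CHIP annotation (`annotate_chip_flag()`) marks calls in clonal
hematopoiesis-associated genes (default DNMT3A, IDH1, IDH2, ASXL1, TET2)
whose precursor VAF is already at least 75% of the MM VAF. Published
descriptions of this phenomenon say only "higher than expected VAFs in
precursor stages"; the 0.75 ratio is this package's explicit, configurable
operationalization, and the flag never filters anything.

## The deep-retest loop

After standard-mode back-tracking, every precursor sample in which at least
one of its patient's variants was *not* significant is planned for deep
resequencing (`plan_deep_retests()`), with exactly those variant keys.
Re-tests rebuild the null from the standard-depth counts — only the
candidate samples were resequenced, not the background panel — and the deep
result supersedes the standard one even when still negative. Pairs already
significant in standard mode are never re-tested.

## Trajectories and cohort summaries

A trajectory records, per variant and timepoint, detection status, VAF, and
the sequencing mode that produced the decisive test. First detection is the
*earliest* significant timepoint (largest months-before-MM); no
interpolation is done between samples, because detection is only defined at
sampled timepoints. First-detection statistics pool over variants, not
patients. Patients fall into `no_variants`, `mm_only` or `precursor_shared`.

The bundled cohort table (21 patients, shipped as `table1.tsv`) carries the
published characteristics: stage at first sample, sex, ages at both
diagnoses, time to progression, serial-sample counts, detection flags and
per-patient mutated-gene lists. Gene spellings are transcribed verbatim —
including the inconsistent forms `IKBK`, `HIST1HE` and `HISTH1D` — with a
normalization map to the panel symbols (IKBKB, HIST1H1E, HIST1H1D) applied
for joins and tallies, so both the faithful transcription and usable keys
coexist. The table lists genes per patient, not per-variant coordinates or
VAFs, so fixture-level variant records are gene-level only.

`summarize_cohort()` reproduces the printed cohort statistics exactly:
21 patients, 68 samples, 48%/52% sex split, 19 MGUS-first vs 2 SMM-first,
6 patients passing through SMM, median ages 67 and 73, median time to
progression 72 months (range 6–166), 29 variants in 20 genes (mean
1.4/patient), 4 patients without variants and 16 with precursor-shared
variants. The mean samples-per-patient is kept at full precision
(68/21 ≈ 3.24) alongside the conventionally rounded "three per patient".
The published median first-detection time (62 months, range 10–103) is
*not* a package-reproducible quantity: it depends on per-variant timepoints
that are only shown graphically, so the package computes the statistic on
its own data but asserts nothing about the published value.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws, per patient, 2–7 timepoints with precursor
sampling months uniform over 6–166 months before MM (matching the published
range and the irregular follow-up of real precursor cohorts), a
Poisson(1.4) number of tracked variants, and an MM-timepoint clone VAF
uniform on 0.02–0.40. Clone dynamics follow a stepwise model: the variant
is absent before a randomly chosen origin timepoint, present there at a
uniform 20–100% of its MM VAF, then grows linearly (logit-linearly under
the `logistic` switch) to the MM value. The published data show
presence/absence and VAF-scaled dots rather than a fitted growth law, so
these dynamics are conventions, not estimates; the origin-VAF floor of 20%
encodes the observation that clones, once sampled as present, tend to be
well within reach of deep sequencing.

Reads are simulated at the allele-count level: depth is negative-binomial
(size 3.5) around the mode's mean — 636× standard, 3410× deep — truncated
at one read, which reproduces a coverage-breadth profile of roughly
99–100%, 96–98% and 85–86% of positions above 30, 150 and 300 reads.
Per-position error rates are drawn once per position from a Beta with mean
$10^{-3}$ (shape 2), and alt reads at a position follow
$\mathrm{Binomial}(d,\; v + e(1-v))$ — the simplest error model in which
background noise is position-specific and shared between patients, which
is exactly the structure the background panel exploits. About 10% of
variants are truly absent from all precursor samples, mirroring the small
minority of patients whose variants appeared only at MM.

Everything is governed by one seed: identical seeds give byte-identical
cohorts.

Not modeled: read-level artifacts (duplicates, strand bias, mapping error),
germline contamination, copy-number effects on VAF, sample-to-sample
contamination, and clonal interference between variants of one patient.
Passing tests therefore demonstrate the statistical behavior of the
decision rule under binomial noise with position-specific error — not
robustness to alignment artifacts, which real studies handle upstream.
Simulated coordinates are arbitrary labels, not genome positions.

## Numerical choices and degenerate inputs

* Sample SD with the $n-1$ denominator: the panel has only 10 members and
  the conservative (wider) estimator is the safer default; a population-SD
  switch exists.
* Strict `>` at the significance threshold and at the coverage threshold;
  `>=` at the VAF and read-guard thresholds — all exercised at their exact
  boundaries in tests.
* A background sample with depth 0 at the position is ineligible; if fewer
  than 10 eligible samples exist the null errors unless `allow_smaller =
  TRUE`, in which case the realized panel size is recorded in the result.
* Frequency at zero depth is undefined (`NaN` from `allele_frequency()`,
  `no_coverage` in detection results), never silently 0.
* Medians over even-sized sets are the midpoint of the central order
  statistics (the bundled cohort has odd $n$, so its printed medians are
  unaffected).
* Depth draws are truncated at 1 read to keep frequencies defined; at mean
  636 the truncation affects a vanishing fraction of draws.

## Problem sizes

The test suite simulates cohorts of 2–21 patients and uses 1,000-replicate
threshold-equivalence checks, 2,000-replicate false-positive and power
suites, and a full 21-patient end-to-end run; the whole suite completes in
about a minute on one core. Parameter-recovery checks run at depth
$10^5$, where binomial noise is small enough to separate implementation
error from sampling error at 3 binomial SDs.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(sim_config(n_patients = 21, seed = 1))
res <- run_pipeline(cohort)

res$summary_counts        # patients by category
res$first_detection       # median/range of months before MM at first detection
plot_trajectories(res$trajectories)

# the bundled study cohort
fx <- load_table1_fixture()
summarize_cohort(fx$patients, fx$variants)
```

## Known limitations

* The background null is a plain mean + 3 SD rule on 10 frequencies; it
  makes no distributional claim and its false-positive rate is controlled
  empirically (the type-I suite), not analytically.
* With 10 background samples the SD estimate is noisy; a variant whose
  background panel happens to include a high-error draw needs a higher
  frequency to clear the threshold.
* The deep-retest loop reuses standard-depth background counts, so deep
  candidate frequencies are compared against a null estimated at lower
  depth; this mirrors the underlying study design but slightly inflates the
  threshold's variance relative to a fully deep panel.
* Gene-level fixture records cannot distinguish two variants in the same
  gene of the same patient; the pipeline itself tracks alleles by
  coordinates, so this limitation is confined to the bundled table.
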