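---
title: "The cis-disruption screen: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cis-disruption screen: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hijackr)
library(dplyr)
```

## The problem

Structural variants (SVs) in cancer genomes can deregulate a gene without
touching the gene itself: a breakpoint that falls between a promoter and a
distal regulatory element severs their chromatin contact on the rearranged
allele, releasing the gene from regulation ("enhancer hijacking" or, as in
the chronic lymphocytic leukemia locus that motivated this package,
release from a restrictive element). Such events are invisible to
coding-mutation callers and too rare per-gene to reach significance in
standard recurrence tests, but they leave a characteristic joint
footprint: a breakpoint inside a promoter interaction, an extreme
expression value in the same donor, and recurrence of that combination
at the same regulatory anchor in other donors.

`hijackr` implements this screen as a chain of tidy, individually
testable stages:

1. **Disruption mapping** — each breakpoint is flanked by ±`flank_bp`
   and intersected with a promoter-capture Hi-C interactome
   (bait/promoter fragment ↔ PIR, the promoter-interacting region).
2. **Expression stage** — raw counts are normalized by median-of-ratios
   size factors; each gene gets a median and interquartile range (IQR)
   across the donors with SV data; each donor's deviation is expressed
   in IQR units.
3. **Candidate stage** — a gene is a candidate if one disrupted donor
   deviates by more than `k_primary` IQR (with a normalized-expression
   floor) and at least `min_recurrent_donors − 1` further donors with a
   disruption at the *same anchor* deviate by more than `k_recurrence`
   IQR.
4. **Survival stage** — candidates are screened by median-split
   Kaplan–Meier / log-rank tests with Benjamini–Hochberg (BH)
   correction over exactly the candidate family.
5. **Concordance stage** — extreme-decile donor groups of a focal gene
   give per-gene fold changes; externally derived gene sets are tested
   for a rank shift (Mann–Whitney U) against the background.

## Coordinates

All in-memory coordinates are 0-based half-open; every external table
(ICGC-style SV files, interaction tables, the published locus notation
`chr14:22370281-22410008`) is 1-based inclusive and converted on read
and write. This removes off-by-one ambiguity from every overlap test:
touching half-open intervals do not overlap, and a breakpoint flanked by
±50 bp is a 101 bp window. Two-ended SV records contribute their two
breakpoints independently (the screen counts breakpoints, not SVs), and
exact duplicates within a donor are removed so that intra-chromosomal
records cannot double-count. Flanked intervals are clamped at the
chromosome origin rather than erroring.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `flank_bp` | 50 | bp | breakpoint flank before intersection |
| `k_primary` | 2 | IQR units | primary outlier threshold (strict `>`) |
| `k_recurrence` | 1 | IQR units | recurrence threshold (strict `>`) |
| `min_norm_expr` | 10 | normalized counts | expression floor on the donor's own value |
| `min_recurrent_donors` | 2 | donors | supporting donors, primary included |
| `padj_threshold` | 0.05 | — | BH-adjusted survival cut |
| `decile_fraction` | 0.10 | — | extreme-group fraction of the concordance stage |

These defaults are the screen's operating point; they are deliberately
conservative in combination (an isolated outlier without an anchor-
sharing second donor is never reported). The floor applies to the
donor's normalized value, not the gene median — it guards against
IQR-unit blow-ups on barely expressed genes, where a handful of counts
can be many IQRs from a near-zero median.

Two structural choices are exposed because the right answer is genuinely
open:

* `disruption_mode`: `"span"` (default) accepts a breakpoint anywhere
  between promoter and anchor — the physical separation argument — and
  is defined for cis interactions only; `"anchor"` requires the hit to
  fall in the PIR fragment itself and also covers trans interactions.
  Anchor-mode events are a subset of span-mode events for cis
  interactions, so `"span"` is the more sensitive screen and `"anchor"`
  the more specific one. Both are first-class and logged.
* `similar_mode`: recurrence requires a second donor at the **same PIR
  anchor** by default (`"shared_anchor"`), reflecting that reported
  candidates attribute all supporting donors to one disrupted anchor;
  `"any_interaction"` relaxes this to any disrupted interaction of the
  gene.

## Numerical conventions

* **Quantiles** are linear interpolations of order statistics (R's type
  7). On small cohorts the convention visibly changes the IQR, so it is
  fixed and tested against a sort-and-interpolate oracle.
* **Outlier direction**: deviations are two-sided with the sign
  retained, since cis-disruption can in principle act both ways;
  `directional = TRUE` restricts to upregulation, the direction the
  motivating locus showed.
* **Zero IQR**: the deviation is `±Inf` off the median and 0 at the
  median. With the expression floor this makes invariant genes callable
  only when genuinely expressed, rather than producing NaNs.
* **All threshold comparisons are strict** (`> 2` IQR, `> 10`
  normalized, `padj < 0.05`), so boundary values never pass.
* **Median split ties** go to the low group; a constant expression
  vector is a degenerate-split error rather than a silent empty group.
* **Decile ties** are resolved by one total order on (value, donor id),
  which keeps the high and low groups disjoint and reproducible even on
  heavily tied data.
* **Fold changes** use group medians with pseudocount 1,
  `log2((med_high + 1)/(med_low + 1))`. The downstream shift test is
  rank-based, so only the ordering of fold changes matters; a
  negative-binomial model would change the values but hardly the ranks,
  and the package deliberately does not re-implement one.
* **Mann–Whitney branches**: exact enumeration up to 20 per side on
  tie-free data, otherwise the normal approximation with tie
  correction.
* **Survival cohorts**: the median split is computed within each cohort
  and the groups are pooled for one log-rank test. The two cohorts the
  screen was built around used different expression platforms; pooling
  raw values across platforms is not meaningful. `pooled_split = TRUE`
  restores the single-split behaviour for homogeneous data. BH
  correction runs over exactly the candidate genes tested in the run.
* Donors present in the survival table but absent from the expression
  matrix (or vice versa) are dropped, with counts reported.

## What the synthetic cohorts emulate

`simulate_cohort()` generates all five inputs with planted ground
truth. Its defaults are the cohort scale the screen targets: 92 donors
contributing 750 breakpoints, 850 interactions annotating 1,700 genes
(two genes per anchor, modelling the shared-anchor topology in which
two promoters contact one regulatory element), negative-binomial counts
(`var = mu + alpha mu^2`, `alpha = 0.1`), donor size factors log-uniform
in [0.5, 2], baseline means log-uniform in [20, 500], an 8-fold planted
cis-effect in 2 donors per planted gene, and exponential overall
survival with hazard ratio 3 between the designated gene's median-split
groups at ~30% independent uniform censoring, with rates in the range
of a median survival of a few years. Where the cohort literature gave
no number (dispersion, size-factor spread, baseline means, hazard
scale) the values are ordinary RNA-seq and survival magnitudes for a
patient cohort, chosen once.

Construction details that make the tests sharp: interaction fragments
never overlap; planted breakpoints fall uniformly inside the planted
gene's anchor, so anchor-mode mapping recovers them by construction;
background breakpoints are placed in the gaps between interaction spans
with a 100 bp margin, so the default ±50 bp flank cannot graze a span
and a background-only cohort maps to zero events. The survival hazard
is tied to the median-split group, not to continuous expression —
exactly the contrast the survival stage tests — and censoring times are
uniform with the scale calibrated so the expected censored fraction
meets the target.

What the generator does **not** emulate: linked copy-number changes,
SV-class structure (deletions vs translocations are equivalent here),
batch effects beyond size factors, platform differences between
cohorts, correlated genes, or realistic breakpoint clustering. Passing
the recovery tests therefore demonstrates that the screen's logic is
correct and calibrated under its stated noise model — not that real
cohorts, with their messier covariance, will yield the same recall.

## Verification sizes

The suite checks, among others: interval and disruption mapping against
brute-force oracles (1,000 random interval pairs; 200 breakpoints × 50
interactions, both modes); median/IQR against a sort-and-interpolate
oracle (500 vectors); BH against the direct step-up formula (100
vectors); the log-rank p against a 20,000-permutation null at n = 20;
type-I error of the survival screen over 500 null replicates at n =
100; power against a hazard ratio of 3 at n = 200 (100 replicates);
uniformity of the shift-test p on 1,000 random null sets; and recovery
of 10 planted genes per cohort over 20 seeds (100 donors, 1,000 genes).
These sizes were chosen to make each check statistically decisive at
desk scale.

## Known limitations

* The screen assumes one genome build across all inputs; lift-over is
  upstream of the package.
* Survival screening is univariate log-rank; no covariate adjustment
  (e.g. mutation status) is attempted.
* `gene_locus` in the output is the gene's bait (promoter) fragment —
  the interaction table carries no gene models.
* With tiny donor scopes the IQR is unstable; `gene_stats()` refuses
  scopes under 4 donors, but 4 is still small — the defaults presume
  cohort-scale input.
* A breakpoint hitting a span shared by many genes produces events for
  all of them; the recurrence-plus-outlier filter, not the mapper, is
  responsible for specificity.
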