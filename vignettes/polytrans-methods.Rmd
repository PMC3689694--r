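---
title: "polytrans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polytrans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytrans)
```

## The model

Polysome profiling yields, per biological replicate, four arrays: the
knockdown and control condition, each measured in the polysomal fraction
(ribosome-loaded mRNA pooled from heavy gradient fractions) and in total
cytoplasmic RNA from the same extract. The analysis rests on one
statistic. For gene *g* and replicate *i*:

$$\mathrm{RR}_i(g) = \frac{\mathrm{polyRNA}_i(g)}{\mathrm{totRNA}_i(g)},
\qquad \mathrm{polyRNA}_i = \frac{\text{kd}_i}{\text{ctrl}_i}\Big|_{\text{poly}},
\quad \mathrm{totRNA}_i = \frac{\text{kd}_i}{\text{ctrl}_i}\Big|_{\text{tot}}.$$

RR isolates the change in polysome association from any change in overall
cytoplasmic abundance. Because RR is a ratio of ratios it is
scale-invariant per sample pair and log-symmetric, which motivates two
choices made throughout: summaries across replicates are **geometric
means** (ratios are multiplicative; the source analysis does not state its
summary, so the log-symmetric one was chosen), and simulated noise is
multiplicative log-normal.

### Assumptions

* Intensities are already normalized (MAS5-style) and background detection
  calls are supplied as flags; the package never recomputes either.
* One row per gene. If the upstream platform reports multiple probesets
  per gene, collapsing is the caller's responsibility.
* Both conditions are present for every (fraction, replicate) pair; the
  pairing is validated and a missing partner is an error naming the pair.

## Filtering, calls, classification

**Detection filter.** A gene enters a fraction's analysis when it is
flagged detected in at least one sample of at least one condition group of
that fraction ("signal above background for one of the compared groups",
with the compared groups read as the condition groups within one RNA
type). Genes retained in neither fraction are dropped; an RR additionally
requires retention in both.

**Calls.** A gene is translationally modified when RR is beyond threshold
*in every replicate* — a concordance rule, not a statistical test; the
source design uses two biological replicates and pure thresholds. The
defaults are up = 1.5 and down = 0.67 with inclusive comparisons (the
reported counts use ≥/≤ even though the methods prose says
"greater/lower"; inclusivity is configurable). At exact boundary values
"modified" wins, i.e. the unmodified band is the open interval
(0.67, 1.5).

**Classification.** The geometric-mean summaries (poly, tot, RR) place
every gene in exactly one class: `POLY_ONLY_*` (poly direction set, total
unchanged), `BUFFERED_*` (total changed, poly unchanged — the class suffix
is the RR direction, so a total *decrease* with constant polysome loading
is `BUFFERED_UP`), `OPPOSITE`, `CONCOMITANT_UNMODIFIED` (both same
direction, RR in band), `OTHER_MODIFIED`, `UNCHANGED`. `OTHER_MODIFIED`
exists because the published per-group counts do not sum to the published
modified total — the partition must be able to represent RR-modified genes
whose (poly, tot) pattern fits no named group (e.g. both directions up
with RR still beyond threshold, or neither direction set while the
quotient crosses the threshold). Classification is a total deterministic
function; no tie-breaking is needed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `up`, `down` | 1.5, 0.67 | fold-change thresholds (dimensionless); 0.67 ≈ 1/1.5 |
| `inclusive` | TRUE | boundary values count as modified |
| `dir_th` | = RR thresholds | separate thresholds for per-fraction directions |
| floor `eps` | 1e-6 × median positive intensity | replaces zero intensities before division |
| qPCR `efficiency` | 2.0 | amplification efficiency E in ratio = E^−ΔΔCt; classic perfect-doubling assumption, per-run configurable since the source protocol states no efficiency correction |
| `flag_dev` | 0.5 cycles | technical Ct replicates deviating more than this from the median are flagged, never dropped (no exclusion rule is stated upstream) |
| `gc_classes`, `length_classes` | 11, 21 | histogram classes for the UTR figures |
| KS `exact_limit` | 10000 | exact p when n1·n2 ≤ limit and tie-free |

## qPCR stage

ΔΔCt with a housekeeping reference: ΔCt = target − reference within each
condition, ΔΔCt = ΔCt(kd) − ΔCt(ctrl), ratio = E^−ΔΔCt. The paired
two-tailed t test of the source design pairs knockdown and control within
each independent experiment; since the pairing is already collapsed into
one ratio per experiment, the faithful equivalent is a one-sample t test
of log(ratio) against 0 with n − 1 df, which is what `ratio_test()`
computes. The geometric mean ratio is reported alongside the arithmetic
SEM of the ratios (the latter matches how validation figures draw error
bars). Zero variance with a nonzero mean log-ratio yields p = 0 with a
degenerate-variance flag rather than an error.

## UTR features and the KS test

GC content is 100·(G+C)/(A+C+G+T), case-insensitive, with N excluded from
both counts (unbiased under ambiguity); an all-N sequence is excluded with
a warning. The exact class boundaries of the published 11 GC / 21 length
histogram classes are not recoverable, so equal-width classes over
[0, 100] (GC) and [0, max length] are used, configurable.

The two-sample KS statistic is the maximum ECDF difference on the pooled
support. The p-value is exact — lattice-path counting of the orderings
whose D stays below the observed one — when n1·n2 ≤ 10000 and the pooled
sample is tie-free; otherwise the asymptotic Kolmogorov series at the
effective sample size ne = n1·n2/(n1+n2) is used. The one-sample
small-sample correction (the √ne + 0.12 + 0.11/√ne form) was evaluated
against the exact computation at n1 = n2 = 100 and found roughly ten
times *less* accurate than the plain √ne·D argument for the two-sample
case, so the plain form is used; exact and asymptotic p then agree within
0.01 at that size (asserted by a simulation test).

## Enrichment stage

The original study's pathway analysis used a proprietary tool with
curated categories; that is not reproducible and is not attempted.
Instead a generic hypergeometric over-representation test against
user-supplied categories is provided: upper-tail p with BH correction,
universe defaulting to the detected genes (standard ORA practice,
configurable). Its results are a stand-in, not a reproduction.

## The synthetic-data generator

`simulate_polysome_dataset()` emulates: study-scale matrices (default
17,416 genes, 2 replicates), log-normal baselines (log2 mean 7, sd 2 —
typical MAS5 intensity scale), multiplicative log2-normal noise (sd 0.1)
on the knockdown samples only (effects are planted on the knockdown
condition, mirroring an siRNA contrast), planted regulation groups at the
published group proportions (326/148 poly-only, 266/131 buffered, 194
opposite, 66 concomitant of 17,416 — scaled proportionally for smaller
runs), and optional MAS5-style absent calls as Bernoulli dropout on
low-intensity cells. Dropout defaults to 0 because the recovery checks
are defined without it. Planted effects are 2.0/0.5; on the log2 scale
the margin to the 1.5 threshold is 0.415, i.e. ≈4 noise SDs for a
replicate-averaged summary, which is what makes exact count recovery the
expected outcome at the default noise.

What a green recovery test establishes: the ratio → RR → call →
classification chain inverts the generator's planted structure exactly
under the generator's own error model. What it does **not** establish:
robustness to features of real arrays the generator omits — probe-level
effects, intensity-dependent variance, normalization artifacts,
correlated replicates, or genes near the thresholds (planted effects sit
well clear of them by design).

`simulate_utr_sets()` draws lengths from one shared log-normal (median
150 nt, sdlog 0.5 — typical human 5'UTR scale) for all three sets and
shifts only the per-base GC probability (+15/−15 percentage points around
0.5 by default), so GC distributions separate while length distributions
differ only by sampling noise. `simulate_qpcr()` plants fold changes as
Ct shifts and adds measurement noise per technical-replicate well; at
zero noise ΔΔCt inverts it exactly, and under the null the log-ratio is
exactly normal, so the t test's type-I error is nominal (checked at
0.05 ± 0.02 over 1000 seeds).

## Numerical choices and degenerate inputs

* Zero intensities are floored, with a warning, to 1e-6 × the median
  positive intensity — preserves ordering, avoids division by zero, and
  keeps the floor far below any biological signal.
* Ratios must be positive and finite after flooring; violations are
  errors, not NA propagation.
* `RR_i × totRNA_i = polyRNA_i` holds to 1e-12 relative tolerance by
  construction and is asserted in tests.
* Empty matrices filter to empty results without error; empty gene lists
  yield k = 0, p = 1 enrichment rows; an all-identical KS input yields
  D = 0, p = 1.
* All simulator outputs are bit-reproducible from (config, seed).

## Known limitations

* Genome-wide counts from the original study (17,416 expressed, 1,151
  modified, the per-group totals) depend on its deposited raw data and
  normalization; the package treats them as reference proportions for the
  simulator, not as reproduction targets.
* The candidate fixture's printed RR column is rounded to one decimal and
  for a few rows disagrees with the quotient of its printed fold changes
  (unrounded upstream values were presumably used); exact arithmetic
  checks are restricted to rows where the quotient and the printed value
  agree.
* No per-gene significance testing of RR (by design — the source method
  is a pure threshold rule); no ANCOVA-style translatome modeling; no
  normalization, probe summarization or GEO retrieval.
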