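---
title: "Contextual similarity for sparse glycopeptide quantification"
author: "glycontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual similarity for sparse glycopeptide quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycontext)
```

## The problem

Site-specific glycosylation is quantified by LC-MS/MS as the elution AUC of
each glycopeptide (a peptide backbone carrying one glycan composition). A
single glycosite hosts many glycoforms, each competing for acquisition time,
so the resulting abundance matrices are small (3–4 replicates), noisy, and
riddled with missing values — an exact zero means "not sampled", not "not
present". Conventional per-feature tests (t-tests, ANOVA) assume more
replicates, less missingness and independent features; none of these hold.
`glycontext` instead compares whole glycosite profiles with a similarity
metric embedded in a permutation (bootstrap) test, asks first whether the
data are good enough to compare at all, and only then whether the two
groups' glycosylation patterns are differentiable — finally ranking the
glycopeptides that drive the difference.

## The weighted similarity metric

For aligned glycopeptides $i$ with per-dataset mean log abundances $A_i$,
$B_i$ and presence rates $P_{i,A}$, $P_{i,B}$ (fraction of replicates in
which $i$ was observed):

$$K_i = 1 + \tfrac{1}{2}(P_{i,A} + P_{i,B}), \qquad d_i = |A_i - B_i|$$

$$T_{\mathrm{mod}} = \frac{\sum_i A_i P_{i,A}\, B_i P_{i,B}\, K_i^{-d_i}}
 {\sum_i (A_i P_{i,A})^2 + \sum_i (B_i P_{i,B})^2 -
  \sum_i A_i P_{i,A}\, B_i P_{i,B}\, K_i^{-d_i}}$$

The presence weights let missingness depress similarity — most strongly the
within-group (Internal) similarity, which enforces a conservative data
quality verdict. The distance term $K_i^{-d_i}$ discounts glycopeptides
whose group abundances differ, and the better a glycopeptide is observed
(larger $K_i$) the more an abundance difference counts. The value always
lies in $[0,1]$; by the AM–GM inequality the numerator never exceeds the
denominator.

Two aggregation choices were genuinely open and are fixed as follows:

* $A_i$ is the **mean of the nonzero** standardized abundances over the
  selected replicates. Missingness is already penalized once through
  $P_i$; averaging zeros in would penalize it twice.
* $K$ is computed **per glycopeptide** from the two presence rates. A
  single global $K$ (one plus the grand mean presence) is available via
  `tanimotoModified(..., kMode = "global")`.
* Two all-zero summaries compare as 1 ("identically nothing") with a
  warning, avoiding 0/0.
* $K_i^{-d_i}$ is evaluated in log space; underflow clamps the term to 0.

## Standardization

Raw ion intensities are log-transformed (base 10 by default; MS intensities
span orders of magnitude) and can be divided per replicate by the log of
its total ion current (TIC). Raw values in $(0,1]$ are rejected rather than
clipped: their logs would be nonpositive and break the metric's sign
contract, and genuine ion intensities are far above 1. Duplicate identifier
rows are summed before the transform (signal split across charge states).
A minimum-total-observation filter (default 2, disable with 0) removes
identifications seen too rarely to say anything about; the two groups are
aligned on the union of identifiers first, with absent rows zero-filled. A
through-origin regression (`estimateGroupScaling`) can estimate a
multiplicative between-group rescaling; it is never applied automatically
because it is an interpretive step, and it is logged loudly when used.

## The four contexts

Replicates are resampled with replacement into *collections* of bootstrap
datasets (canonicalized as sorted index multisets; duplicates removed):

* **Internal A / Internal B** — all pairs within one group's collection:
  how much a group resembles itself. 100 samplings per group by default
  (at most `choose(100, 2)` = 4950 comparisons; with 4 replicates the
  number of distinct multisets caps at 35).
* **Test** — all cross pairs between the two groups' collections (at most
  10 000): how much the groups resemble each other.
* **Null** — cross pairs of two collections drawn from the *pooled*
  replicates, each draw balanced between the groups to within one
  (200 samplings per side, at most 40 000 comparisons): what "no
  difference" looks like for these data.
* **Observed** — the single unsampled comparison, used to check that the
  bootstrap actually simulates the original comparison (valid when within
  3 SD of the Test mean, or within its central quartiles in the stricter
  mode).

One seeded RNG stream drives all sampling (test A, test B, null), so the
whole pipeline is bit-reproducible from a single seed.

## Overlap rates, Internal Confidence, and the verdict

Distribution overlap is measured on Gaussian-kernel densities (512-point
grid on $[-0.05, 1.05]$, clipped to $[0,1]$ and renormalized; Silverman
bandwidth floored at $10^{-3}$; zero-spread samples become flagged spikes).
With $T$ the Test density, $R$ the reference density and $x$ the first
point between the two means at which $T$ drops below $R$ (midpoint
fallback when they never cross there):

$$\alpha = \frac{\int_x^1 T}{2 - (\int_x^1 T + \int_0^x R)}, \qquad
  \beta  = \frac{\int_0^x R}{2 - (\int_x^1 T + \int_0^x R)}$$

Disjoint densities give $\alpha=\beta=0$; identical ones give
$\alpha=\beta=0.5$. These play the role of false positive and false
negative rates. A group's **Internal Confidence** is

$$IC = \frac{\mu_{\mathrm{Internal}} - \mu_{\mathrm{Test}}}
            {\sigma_{\mathrm{Internal}}}\times 10^{-(\alpha+\beta)}$$

kept *signed*: a negative IC means the group coheres less with itself than
with the other group (the samples may not be replicates), and both ICs
near zero mean everything plausibly stems from one glycosylation pattern.
An IC of 2 (the default gate; raise it to be more conservative)
corresponds to a one-sided normal tail below 5%.

The groups are declared differentiable when the Test-vs-Null overlap has
$\alpha < 0.05$ and $\beta < 0.20$. The declared status resolves in this
order: both ICs close to zero (|IC| < 1) and no Test/Null separation →
`not_differentiable` (same underlying pattern); either group failing its
quality gate (IC below 2, or Internal-vs-Test $\alpha \ge 0.05$ /
$\beta \ge 0.20$) → `quality_insufficient` (a separation may exist but
cannot be trusted); otherwise the Test-vs-Null decision stands. A Null
mean below the Test mean is flagged as a sanity signal (very high internal
variability, low missingness).

## Replicate outliers

A multimodal Internal distribution indicates that comparisons involving
some replicate behave differently. Peaks of the density (local maxima with
prominence at least 5% of the maximum) partition comparisons into basins;
peaks holding more than 10% of comparisons are examined. A replicate's
*membership* in a peak is the fraction of in-peak comparisons whose
samplings contain it, z-scored against the leave-one-out mean and SD of
the other replicates; |z| > 3 (a < 1% two-sided normal tail) marks over-
or under-representation. Two numerical choices differ deliberately from a
naive transcription:

* the leave-one-out SD is floored at the binomial standard error of the
  mean membership over the distinct samplings in the peak — with only
  three remaining replicates the raw SD can be arbitrarily close to zero
  by chance, which otherwise flags interchangeable replicates constantly;
* the **primary** peak is the *highest-similarity* peak above the mass
  gate, not the largest. With replacement sampling at 3–4 replicates a
  degraded replicate enters ~90% of comparisons, so the largest mode is
  typically the contaminated one; the high-similarity mode is the group's
  coherent core, which is what "under-represented in the primary peak"
  is meant to interrogate.

Removal is recommended only for under-representation in the primary peak
or over-representation elsewhere, and `runComparison()` reruns exactly
once without the recommended replicates (no iterative removal — that way
lies data dredging). The machinery cannot split genuine subgroups within
a sample group; multimodality that survives removal means the comparison
should not proceed.

A candid limitation, established with this package's own simulations: at a
realistic replicate noise of 0.3 log units, a replicate that loses half
its observations shifts the affected comparisons by only about one
within-mode SD, so the Internal density stays effectively unimodal and
detection power is low. The degraded replicate *is* reliably detected when
replicate noise is small (≤ 0.15 log units), where the contaminated and
clean modes separate. Detection specificity is excellent in both regimes
(no flags on interchangeable replicates in 20/20 seeded runs).

## Ranking

Per glycopeptide, each Test-comparison contribution (the numerator term
only — the denominator is biased by missing values, which occur more in
Null-type datasets) is z-scored against its Null contribution
distribution; the ranking statistic is the mean of those z-scores, sorted
ascending (ties broken by identifier). Scores below −2 mark strong
differentiation drivers, though missingness can raise them; markedly
positive scores suggest interdependence between the datasets. Each
glycopeptide also gets a quality verdict by the overlap of its Internal
versus Test contribution distributions (per group, after a joint rescale
to the unit interval), with $\alpha + \beta \ge 0.25$ failing — the same
semantics as the global gates, combined into one threshold because the
per-glycopeptide distributions are coarse. Failure causes are reported
with precedence: unseen in a group (`UnseenIn_File1/2`), degenerate Null
contributions (`DegenerateNull`), low quality in both or one group, else
`Passed`. Note that "Passed" requires the glycopeptide's cross-group
behavior to be *distinguishable* from its within-group behavior: a
glycopeptide identical in both groups cannot separate the two and fails,
by design, exactly as a glycosite with one pattern fails the global gate.
A glycopeptide absent from both groups is dropped, never ranked.

## The synthetic-data generator

`simulateScenario()` emulates the structure of glycosite-level
quantification without modeling chromatography or spectra: per
glycopeptide a base log10 abundance uniform on (4, 8) (ion intensities
10^4–10^8), Gaussian replicate noise (default SD 0.3 log units, roughly a
2-fold intensity spread), i.i.d. Bernoulli dropout to per-glycopeptide
presence rates (default uniform on 0.39–0.80, the range seen in real
glycosite datasets), 4 replicates per group, 30 glycopeptides. Effects:
group-exclusive sets (`exclusive_set`), multiplicative shifts
(`uniform_shift`), permuted patterns (`pattern_shift`), and a degraded
replicate losing a fraction of its observations. `presetScenario()` fixes
the canonical study conditions used by the tests and the acceptance
script; the exclusive preset makes 9 of 30 glycopeptides (30%, as in a
purified-versus-complex-mixture comparison) exclusive to group A with
full presence elsewhere; the variability preset triples the noise.

What the generator does **not** emulate: abundance-dependent dropout
(low-abundance ions are likelier to be missed in real DDA data),
correlated missingness across glycopeptides, biosynthetic dependence
among glycoforms, and retention-time or charge-state artifacts. Passing
simulations therefore demonstrate the machinery's operating
characteristics under clean assumptions, not performance on any
particular instrument's data.

Two finite-sample behaviors of the contextual design are worth knowing.
First, at zero effect the Internal distributions sit systematically above
the Test distribution (internal comparisons resample the *same* realized
cells; test comparisons span two independent realizations), so no-effect
ICs land around 0.5–1.5 rather than at zero; the IC gate of 2 is what
separates this regime from genuinely coherent data. Second, with sparse
presence and 4 replicates, chance pattern differences can separate Test
from Null on the raw overlap alone in a sizable fraction of null
datasets — it is the IC quality gate, folded into the declared status,
that keeps the tool's no-effect false declaration rate at zero in the
packaged simulations.

## Problem sizes and reproducibility

The packaged simulation studies run 20 seeds per scenario at bootstrap
depth 50 test / 100 null samplings; the acceptance script runs the
canonical scenarios at the full default depth (100/200, up to 40 000 null
comparisons) plus 10-seed operating-characteristic sweeps. All randomness
flows from one user-supplied seed; two runs with the same seed produce
byte-identical reports.

```{r example, eval = FALSE}
sc <- simulateScenario(presetScenario("exclusive", seed = 7))
res <- runComparison(sc$a, sc$b, seed = 7, outDir = "results_ex")
res$report
head(res$ranking)
```
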