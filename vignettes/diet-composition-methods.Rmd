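---
title: "Methods: diet composition, rank-based comparisons and the synthetic survey generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet composition, rank-based comparisons and the synthetic survey generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gekkodiet)
```

gekkodiet analyses stomach-flushing surveys of insectivorous lizards. This
vignette documents the models and conventions behind each computation, the
tunable parameters and their defaults, what the synthetic generator does and
does not emulate, and the numerical choices a maintainer should know about.

## Prey volume

Prey items recovered by stomach flushing are measured for maximum length
$L$ and maximum width $W$ (to 0.1 mm). Volume is estimated by treating the
item as a prolate spheroid of revolution:

$$V = \frac{4\pi}{3}\,\frac{L}{2}\left(\frac{W}{2}\right)^2 \quad [\mathrm{mm}^3]$$

This is the standard approximation for elongated invertebrate prey. The
classical field formula fixes $\pi = 3.14$; `prey_volume()` defaults to full
floating-point precision and offers `pi_mode = "3.14"` for exact
back-compatibility with older worksheets. The choice never affects
percentage columns or the IRI, because the constant cancels in every ratio
(a property the test suite asserts).

Width is *not* required to be smaller than length: curled or telescoped prey
can legitimately measure wider than long, so `read_prey_table()` warns on
such rows but keeps them. Dropping measured items silently would bias
composition; an error would block ingestion of real field sheets.

## The composition table and the IRI

For each prey category the table reports F (number of stomachs containing at
least one item of the category), N (number of items) and V (summed item
volume), plus percentage columns and the Index of Relative Importance,

$$\mathrm{IRI} = \frac{\%F + \%N + \%V}{3},$$

computed from *unrounded* percentages. Rounding (half away from zero, two
decimals) happens only at presentation and export; this is the only
convention under which a published 22-category reference table reproduces
cell-for-cell, and it keeps stored objects exact for downstream arithmetic.

Two `%F` denominator conventions coexist in the diet literature:

* `sum_of_F` (default): each category's occurrences over the summed
  occurrences of all categories. The columns then all sum to 100 and the IRI
  column does too, which is how the bundled *C. nigriocularis* table is
  normalised (Araneae: $100 \cdot 20 / 75 = 26.67$).
* `n_stomachs`: occurrences over the number of stomachs analysed, the more
  literal reading of "frequency of occurrence". Columns no longer sum
  to 100.

Both are first-class options; results state which was used.

### Ranking and the recurrent-category filter

`rank_by_iri()` orders categories by non-increasing IRI, breaking ties by
descending N and then alphabetically (ties are rare in practice; the
deterministic rule simply makes output stable). The `min_F` argument drops
categories found in fewer than `min_F` stomachs before ranking. The
motivation: a category recovered from a single stomach can ride a large
volumetric share to a high IRI (in the bundled table, earthworms at
IRI 5.93 and a whip scorpion at 5.64 each come from one stomach), yet such
categories are incidental captures, and headline "most important prey"
lists in diet studies are typically restricted to recurrent categories.
With `min_F = 2` the bundled table yields the six-category ranking
Araneae, Opiliones, Achatinidae, Blattidae, Scolopendridae, Acrididae; the
strict default (`min_F = 1`) interleaves the two single-stomach categories
at ranks 6-7.

```{r ranking}
comp <- composition_from_counts(nigriocularis_composition())
rank_by_iri(comp, top_k = 8)
rank_by_iri(comp, top_k = 6, min_F = 2)
```

## Rank-based comparisons

Diet metrics are compared between sexes (male vs female) or age classes
(adult vs subadult) with the two-independent-sample Wilcoxon rank-sum
(Mann-Whitney) test; per-item metrics pool items within a group, per-stomach
metrics aggregate to one value per specimen first. Both statistic
conventions are reported — the rank sum $W$ of the first sample and
$U = W - n_a(n_a+1)/2$ — because published tables are inconsistent about
which they print.

The two-sided p-value is exact (the full null distribution of $U$ over all
$\binom{n_a+n_b}{n_a}$ rank assignments) whenever the data are tie-free and
$n_a n_b \le 400$; beyond that, or with ties, a normal approximation with
tie-corrected variance and a 0.5 continuity correction is used. The
threshold keeps the exact path instantaneous while covering every sample
size where the approximation is materially worse: computed exhaustively over
all possible $U$ for every size in the exact regime, the approximate
two-sided p is within 0.02 of the exact one once $\min(n_a, n_b) \ge 5$, but
the discrepancy grows to 0.0375 at $3 \times 3$ and 0.088 at $2 \times 2$ —
sizes that, by the threshold, never reach the approximate branch.

Kendall's $\tau_b$ (for body size vs prey volume relationships) applies tie
correction in both margins; its exact null for tie-free $n \le 10$ is
enumerated via the inversion-count (Mahonian) distribution, and larger or
tied samples use the standard tie-corrected variance of $S$ with a one-unit
continuity correction. Pearson correlation and simple linear regression
(for morphometric relationships) delegate to `stats::cor.test()` and
`stats::lm()`.

All tests are two-sided, and no multiple-testing adjustment is applied by
default — matching how such surveys are conventionally reported — with Holm
adjustment available via `p_adjust = "holm"`.

## Uncorrected p-distance

`p_distance()` computes the proportion of differing sites between two
aligned sequences. Columns with a gap in either sequence are always
excluded. Ambiguity codes follow one of two policies:

* `pairwise_delete` (default): columns containing any ambiguity code in
  either sequence are excluded, the usual convention for uncorrected
  distances;
* `mismatch_if_incompatible`: ambiguous columns are kept and count as a
  mismatch only when the two IUPAC sets are disjoint (R vs G is compatible,
  R vs C is not).

Percent divergences are reported to two decimals. On a gap-free alignment
p-distance is a metric (identity, symmetry, triangle inequality), which the
suite asserts on random fixtures; model-corrected distances and tree
inference are deliberately out of scope.

## The synthetic survey generator

The generator exists so that every pipeline stage — ingestion, composition,
comparison, reporting — is testable at survey scale without any field data.
Its defaults emulate the motivating survey:

| Component | Model | Default |
|---|---|---|
| Group sizes | fixed | 15 male / 33 female / 3 subadult |
| Morphometrics (SVL, MW, BM per group) | correlated trivariate log-normal, moment-matched per margin | group means/SDs of the survey; log-scale correlations 0.860 / 0.948 / 0.833 |
| Items per stomach | zero-truncated negative binomial, moment-matched | mean 7.98, SD 8.42 |
| Prey category | i.i.d. multinomial | probabilities proportional to the 22 observed item counts |
| Item dimensions | per-category log-normal, calibrated | pooled length 7.53 ± 6.55 mm, width 1.44 ± 1.10 mm |

Design notes, in the order the data are built:

**Morphometrics.** Means and SDs are matched exactly on the raw scale via
log-normal moment inversion, with the configured correlations applied on the
log scale (the scale the published scatter plots do not disambiguate; the
choice is documented as approximate). Draws are rejected outside a
configurable per-trait envelope. The default envelope is
$\mathrm{median} \cdot e^{\pm 3.5\sigma_{\log}}$ rather than the observed
group minima and maxima: the observed ranges come from 3-33 animals and are
narrower than any distribution matching the configured SDs could support —
for the subadults (n = 3) the observed half-range is *smaller than the SD*,
which no bounded distribution can satisfy — so a wide symmetric-on-log-scale
sanity envelope preserves the moments (recovered within 3 standard errors at
n = 10,000, asserted in the suite) while still excluding absurd values.

**Stomach counts.** The survey's SD exceeds its mean (8.42 > 7.98), ruling
out Poisson; a negative binomial is the minimal two-parameter family. Every
sampled stomach contained food, so the *zero-truncated* distribution is
moment-matched to the targets (solved numerically at configuration time,
deterministically), and sampling inverts the truncated CDF.

**Item dimensions.** Per-category relative length scales derive from the
observed mean item volume per category ($V/N$): for a roughly constant
width/length aspect, volume scales as length cubed, so
$L_c \propto (V_c/N_c)^{1/3}$ — making large-bodied categories (earthworms,
giant land snails) generate large items. Within a category, length is
log-normal around its scale; width is log-normal around a global aspect
times the category's mean length (widths cannot inherit the full item-level
length variance, or the pooled width SD target would be unattainable).
Closed-form moment matching sets the global scale and spread; a short
deterministic simulation refinement (three iterations at n = 40,000 under a
fixed internal seed) absorbs what the closed form cannot see — measurement
rounding to 0.1 mm and the enforcement of $W \le L$ by width resampling.
Pooled means and SDs are then recovered within 3 standard errors at
n ≈ 10,000 items (asserted in the suite, with the SD's standard error
computed from the sample kurtosis, since the dimensions are heavy-tailed).

**Group effects.** By default the sexes are exchangeable in everything
except their morphometrics — there is no built-in prey-size difference, so
the default configuration is a proper null for the comparison pipeline (its
type-I error over 100 replicate surveys is asserted to sit inside the
central 95% binomial band around $\alpha = 0.05$). The intersexual
differences reported in real surveys are emulated explicitly, e.g.
`group_effects = list(length_shift_sd = c(female = 1))` shifts female item
lengths by one within-category log-SD; that configuration is detected by the
Wilcoxon comparison in over 80% of replicate surveys at the survey's sample
sizes.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: no seasonal or spatial structure (the
motivating survey is a single September sample from three transects), no
capture-probability or size-biased detection, no digestion-state
measurement error, no within-stomach category clustering (categories are
i.i.d. across items, whereas real stomachs plausibly contain correlated
prey), and per-category size distributions are constrained only by pooled
moments and per-category mean volumes, not by observed per-category spreads
(which are unpublished).

## Numerical choices and degenerate inputs

* Presentation rounding is half away from zero with a $10^{-9}$ guard
  against binary representation of exact halves; stored values are never
  rounded.
* Sample SDs use the $n-1$ denominator; a single observation reports SD 0
  with n = 1 visible.
* Exact-test thresholds ($n_a n_b \le 400$ for the rank-sum, $n \le 10$
  tie-free for $\tau_b$) keep enumeration far under a second and determinism
  at test scale.
* Constant inputs to correlation/regression raise a typed degenerate-input
  error naming the offending vector; all-gap sequence pairs raise an
  undefined-distance error rather than returning NaN.
* Problem sizes used by the suite: the composition reference table is 22
  rows (instantaneous); error-rate and power checks use 100 replicate
  surveys at the survey's own sample sizes; moment-recovery checks use
  10,000 specimens / ~10,000 items.

## Known limitations

* The `%F` convention must be chosen knowingly: the two denominators give
  different percentages (26.67 vs 39.2 for the bundled table's spiders) and
  only `sum_of_F` makes the IRI column sum to 100.
* One `%V` cell of the bundled reference table differs from its published
  value by one unit in the last decimal because the published V column is
  itself rounded; the package reproduces the published IRI column exactly.
* Rank-sum p-values with heavy ties rely on the normal approximation
  regardless of sample size; with very small, very tied samples no good
  option exists and `method_detail` says which path was taken.
* The p-distance module checks conspecificity only; it deliberately offers
  no substitution-model correction, so its percentages understate divergence
  for anything but closely related sequences.
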