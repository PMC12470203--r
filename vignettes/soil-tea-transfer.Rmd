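---
title: "Methods: tracing Cd and Se from soil to tea infusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing Cd and Se from soil to tea infusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teatrace)
```

## The transfer model

`teatrace` treats a tea garden as a chain of compartments — soil, six tea
tree organs, and the brewed infusion — and quantifies each hand-off with a
ratio index. The underlying assumption is multiplicative attenuation: the
concentration in a distal compartment is, up to biological noise, its
proximal neighbour's concentration times a transport coefficient. That
assumption is what makes the algebra of the indices composable: transport
coefficients telescope (the product of TCs along fibrous root → taproot →
main stem → lateral stem equals the lateral stem / fibrous root
concentration ratio exactly), and the ratio of two organs' enrichment
coefficients equals the transport coefficient between them. Both identities
are enforced as property tests.

The sanctioned chain is fibrous root → taproot → main stem → lateral stem,
with *both* leaf classes attached to the lateral stem, and the infusion
terminal after the young leaf. Old and young leaves branch from the same
parent because the lateral stem is where leaf-bound Cd is partitioned;
asking for a transport coefficient between non-adjacent organs is a
contract error rather than a silently computed nonsense ratio.

Aggregation order matters and is fixed throughout: indices are computed per
replicate, averaged to a site value, and site values are averaged across
sites — a *mean of ratios*, not a ratio of means. The two differ whenever
replicate concentrations vary, and only the former reproduces the reference
survey's printed chain means (0.29, 0.97, 1.16 for the stem steps) from its
per-site tables.

### Units

Totals are stored in mg kg⁻¹, available fractions in µg kg⁻¹ and infusions
in µg L⁻¹ — the units in which such tables are printed — and every
µg ↔ mg conversion (factor 1000) happens inside exactly one index formula,
never at rest. `activation_rate(x * 1000, x)` returning exactly 100 % is
kept as a sentinel test. The leaching rate converts both sides to element
mass: `(C_inf × V)` µg in the cup over `(C_tea × m × 1000)` µg in the dry
leaf.

## The risk chain

The carcinogenic model is the standard two-step exposure chain:

* `D = I · Ci · μ / W` — daily dose per unit body weight, with tea intake
  `I = 0.0114` kg d⁻¹, body weight `W = 70` kg;
* `R = (1 − exp(−D·q)) / 70` — average individual annual risk, with the Cd
  carcinogenic intensity coefficient `q = 6.1`.

The divisor 70 appears twice with two different meanings (body weight;
annual-averaging constant). They are deliberately *independent* parameters
of `risk_params()`, both defaulting to 70, so neither can silently absorb
the other. `μ` is a fraction internally; `risk_table()` accepts the
percent-valued leaching columns that survey tables carry and divides by
100 at that boundary, announcing it with a message.

Numerically, `1 − exp(−x)` is computed as `-expm1(-x)`: at realistic tea
doses (`D ≈ 10⁻⁷`–`10⁻⁶`) the naive form loses up to half the significant
digits to cancellation. At these magnitudes the model is linear in the
dose to within `D·q/2` relative error (≈ 10⁻⁶ at measured-leaching doses),
which licenses the μ-linearity identity `R(Ci, μ) ≈ μ · R(Ci, 1)` used to
validate published per-site risks when the unrounded tea concentrations
behind them are unavailable. The identity is exact enough to reproduce
3-significant-digit published values; tests assert the 10⁻⁵ relative
linearization bound on the dose range where it genuinely holds
(`D ≲ 3 × 10⁻⁶`; the error scale `D·q/2` makes it provably false much
above that).

## The statistical layer

**Correlation.** `pearson_matrix()` uses pairwise-complete observations,
p-values from `t = r√((n−2)/(1−r²))`, and the plain star convention
(`*` p ≤ 0.05, `**` p ≤ 0.01). No multiple-testing correction is applied
anywhere in the package — the field convention for these survey
correlation panels — so stars are descriptive, not confirmatory.

**ANOVA and letters.** `anova_lsd()` runs the omnibus one-way ANOVA (via
`stats::lm`/`anova`) and, *only* when it is significant, all pairwise LSD
tests at the pooled error mean square — Fisher's protected LSD, chosen as
the textbook default and because protection suppresses spurious letter
splits. Letters come from insert-and-absorb over the pairwise decision
graph with groups sorted by descending mean, so the largest mean always
carries `a`. The display satisfies, and is exhaustively tested for up to
six groups to satisfy, the partition property: two groups share a letter
exactly when their LSD test does not reject.

`anova_from_summary()` rebuilds the between/within sums of squares from
per-group (mean, sd, n) with exact algebra — `SSB = Σ nᵢ(mᵢ − m̄)²`,
`SSW = Σ (nᵢ−1)sᵢ²` — and then shares the entire post-hoc path. On
summaries of raw data it is algebraically identical to `anova_lsd()` (a
tested invariant), which is what lets published mean ± sd tables be
re-lettered without the raw replicates. Degenerate inputs are defined,
not accidental: all groups identical gives `F = NA` and a common letter;
zero within-group variance with distinct means gives `p = 0` and an LSD
of zero, so any difference separates.

**Two-phase regression.** `threshold_fit()` fits two *independent* OLS
lines below and above a breakpoint — a discontinuous two-phase model, not
a continuity-constrained broken stick, because the threshold effects it
targets are reported as two separate fits. In search mode the breakpoint
grid is the midpoints between consecutive sorted unique predictor values:
any breakpoint between the same two data points yields the same partition,
so midpoints enumerate all distinct models without an infinite candidate
set. Each admissible split must leave ≥ 3 points per side (an OLS line
through fewer is unidentifiable in any useful sense); ties in total SSE
break toward the smaller breakpoint, deterministically. The searched SSE
can never exceed the SSE at any fixed breakpoint, including the generating
truth — a tested invariant.

Whether a threshold like the 2.0 mg kg⁻¹ fibrous-root Se switch is an a
priori constant or should be estimated is genuinely open; both modes are
first-class (`breakpoint = 2.0` vs `breakpoint = NULL`), and the pipeline
exposes the choice. No automatic outlier exclusion is performed — the
exclusion rules behind published "abnormal point" flags are rarely stated,
so rows must be excluded in the input, visibly.

**Normality screening** (Shapiro–Wilk or any standard routine) is advisory
in this design: it never gates or alters results, and is left to the user
(`stats::shapiro.test` works directly on the replicate columns).

## The synthetic generator

`simulate_study()` exists so that every estimator in the package can be
checked against a known truth. It emulates the structure of a 12-garden,
3-replicate survey:

* soil totals uniform in the survey ranges (Cd 0.18–0.55, Se 1.46–5.50
  mg kg⁻¹);
* available fractions via a lognormal site-level activation rate (mean
  20.93 % for Cd, 2.27 % for Se, CV 0.35 — the survey's per-site ARCd
  spread of roughly 6–36 % around its mean motivates that CV);
* fibrous-root Cd anchored at `soil Cd × EC` (EC 3.49) plus a piecewise
  Se-coupling, positive below 2.0 mg kg⁻¹ fibrous-root Se and negative
  above. The coupling slopes (+0.4 / −0.3) are in enrichment-ratio units,
  i.e. the additive concentration term carries the site's soil Cd; this
  makes the soil-normalized fibrous-root response exactly piecewise linear
  in Se with the configured slopes — the estimable quantity — rather than
  a relationship whose slope varies threefold with the site's soil Cd;
* downstream organs multiplied along the TC chains (Cd: 0.29, 0.97, 1.16,
  0.26, 0.07; Se: 0.51, 0.72, 0.63, 2.00, 0.95 — the latter derived from
  the survey's organ Se means) with lognormal replicate noise, CV 0.05,
  mean-corrected (`exp(σz − σ²/2)`) so configured coefficients are also
  the expected estimates;
* infusion concentrations from the latent young-leaf value and a lognormal
  site leaching rate (mean 13.33 %, CV 0.25 — the survey's 13.33 ± 3.86
  spread);
* soil covariates (pH, SOM, TN, TP, AP, AK) with plausible acid-tea-soil
  marginals, tied to the activation latent through a one-factor Gaussian
  copula with signed loadings (pH −0.6, AK +0.5, TN +0.4) so that
  correlation-sign analyses have something real to find. Magnitudes are
  free parameters and claim no fidelity.

Because the threshold coupling rides multiplicatively on soil Cd, scaling
the configured fibrous EC by *k* scales the estimated EC by *k* only when
the coupling is switched off; the linearity-of-estimator test therefore
sets the coupling slopes to zero. Slope-sign recovery is a distributional
property — with 12 sites and only ~40 % of them below the breakpoint,
individual seeds can and do produce a flat below-segment — so it is
asserted as ≥ 18 of 20 seeds at the ground-truth breakpoint, while
single-seed tests pin the searched breakpoint to within one grid step.

What the generator does **not** emulate: spatial autocorrelation between
gardens, separable quadrat/plant/assay variance components (one replicate
CV stands in for all levels), measurement censoring at the LOQ, and any
mechanistic soil chemistry. Passing recovery tests therefore demonstrates
that the estimators are consistent under the assumed multiplicative model
— not that real tea gardens obey it.

## Reference fixtures and reproduction

The bundled twelve-garden survey enters as printed summary tables (site
mean ± sd, n = 3). Re-deriving indices from rounded site means reproduces
the published cross-site summaries to about one unit in the last printed
decimal (e.g. the taproot → main stem chain mean computes to 0.98 against
a printed 0.97); quantities that were computed from unrounded replicates
upstream of printing — the fibrous-root EC of 3.49, the pooled activation
rate — are validated from the printed per-site *index* columns instead,
which is why the soil fixture carries ARCd/ARSe/Pi columns alongside the
raw pools. Per-site forward risks cannot be recomputed from the rounded
organ table at all (young-leaf Cd is printed to 2 d.p.); they are
validated through the μ-linearity identity instead, inverting the
total-transfer risk to the implied tea concentration.

Problem sizes are deliberately desk-scale: the survey fixtures are
12 × 6 × 2 tables, synthetic studies default to 12 sites × 3 replicates,
recovery studies use 20 seeds, and the two-phase recovery example uses
n = 60 — the full test suite and the acceptance script each run in
seconds.

## Known limitations

* The pipeline computes leaching rates from its own inputs (infusion over
  young-leaf concentration); published per-site leaching columns are not
  exactly consistent with published rounded organ tables (processed green
  tea is not identical to fresh young leaves), so file-input runs on the
  bundled study show higher recomputed leaching (~16.7 %) than the printed
  column (13.33 %). Both are available; they answer different questions.
* Letters require replicate structure: a study carrying one value per site
  yields no letter columns (use `anova_from_summary()` on the summary
  tables instead).
* Se is traced through every index but has no risk model — Se intake is a
  benefit/deficiency problem, not a carcinogenic one, and a Se run of the
  pipeline skips the risk stage with a logged notice.
* `Pi` classes and the ICRP 5 × 10⁻⁵ comparison are report-level
  annotations, not hard invariants.
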