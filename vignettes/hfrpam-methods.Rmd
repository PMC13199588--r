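---
title: "Methods: expert-elicitation risk probability assessment for physical literacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expert-elicitation risk probability assessment for physical literacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfrpam)
```

## The model and its assumptions

`hfrpam` quantifies the risk that the *human factors* of physical
literacy (PL) pose to physical-activity implementation, from a single
cross-sectional expert panel. The factor structure is fixed a priori:
Whitehead's two-stage / six-attribute PL construct as operationalized by
the 18-item PPLI, coded `X1` (core stage) with children `X2`–`X4` and
`X5` (external stage) with children `X6`–`X8`. The package does **not**
learn this structure from data — the stage membership and parent links
are the model's antecedent assumptions, and the Bayesian stage uses them
only to define counting groups, not to fit a network.

The input is an `n x 8` matrix of integer Likert ratings in 1–5, where
each expert rates how strongly each factor correlates with risk to
physical activity. Three further assumptions are load-bearing:

* **Ordinal anchoring.** Ratings are exchangeable within the three
  correlation levels low (≤ 2), medium (= 3), high (≥ 4); all risk
  counting happens at level granularity, so the distinction between a 4
  and a 5 never reaches the posterior.
* **Complete data.** Missing cells are rejected, not imputed. The
  elicitation design this model comes from achieved complete response;
  silently imputing expert judgments would manufacture consensus, so an
  incomplete panel is a data-collection problem, not an estimation
  problem.
* **One-shot elicitation.** Everything is computed from one rating
  occasion (plus an optional retest occasion for the ICC). No
  chain-based convergence diagnostics apply to this design and none are
  computed.

## Stage by stage

### Quality control

Cronbach's α (item-variance form, sample variances with denominator
n−1), I-CVI/S-CVI, ICC and per-factor moments. Conventions that the
literature leaves open were fixed as follows:

* **ICC form = ICC(2,1)** — two-way random effects, absolute agreement,
  single measurement: the standard choice for a test–retest design with
  two administrations, computed from the two-way ANOVA mean squares with
  McGraw–Wong confidence intervals. "Test–retest ICC" alone does not
  pin down a form; (2,1) is the defensible default.
* **CVI relevance floor = rating ≥ 4** on the 5-point scale. Classical
  CVI uses the top two categories of a 4-point relevance scale; on a
  5-point instrument the top two categories are 4 and 5. The floor is an
  argument, not a constant.
* **S-CVI uses the averaging convention** (mean of I-CVIs), not the
  universal-agreement variant, which is systematically lower and rarely
  what "S-CVI ≥ 0.9" thresholds refer to. The choice is flagged here
  because reported S-CVIs are not comparable across the two variants.
* **Skewness** is adjusted Fisher–Pearson `G1`; **kurtosis** is plain
  (non-excess) `m4/m2^2`, matching the screening thresholds |skew| < 3,
  |kurt| < 10. A constant column has undefined shape moments; they are
  reported as 0 with a `degenerate` flag rather than NaN.

QC violations warn and never abort: the QC stage describes the panel, it
does not gate the pipeline.

### Counting-based risk posteriors

For factor `f` and level `ℓ`: the prior is the share of level-`ℓ` cells
in `f`'s stage group (primary factor + its three children, `4n` cells);
the likelihood is `f`'s own level count over the pooled six secondary
columns (`6n` cells); then

`inverse = 1 − likelihood`,
`marginal = prior·likelihood + (1 − prior)·inverse`,
`posterior = prior·likelihood / marginal`.

Two deliberate design points:

* **The marginal is the complement mixture, not a textbook
  marginalization over levels.** It is implemented as designed because
  the banded outputs this model is known by are defined in terms of it.
  A `canonical` option (marginal = Σ over levels of prior·likelihood,
  posteriors summing to 1 per factor) is provided for comparison and is
  off by default.
* **Denominators are configurable** (`prior_group`, `likelihood_cells`).
  The counting bases are described in spreadsheet terms in the source
  methodology and cannot be fully disambiguated without the raw panel.
  The default reading — prior pooled over the stage group, likelihood
  per-column over the secondary pool — is the one that reproduces the
  scheme's boundary behaviour exactly: a panel of all 5s gives posterior
  1 (prior mass 1 forces the update to certainty) and a panel of all 1s
  gives posterior 0 at the high level. A per-column prior (count of the
  factor's own column over the stage-group cells) caps the prior at 0.25
  and cannot produce either, so it was rejected.

Banding: low `p ≤ 0.4`, medium `0.4 < p < 0.8`, high `p ≥ 0.8`. The
published band quotes the high band as starting at 0.81, leaving
[0.80, 0.81) unlabeled; since the bands are built from equidistant 0.2
steps, the high band is closed downward at 0.8 so labels partition
[0, 1]. A zero marginal yields an explicit `undefined` flag.

### Entropy-reduction weights

The entropy-weight method rewards dispersion: factors the experts
disagree on carry more discriminating information. The source recipe
normalizes each column by its range (max − min); applied literally, the
resulting shares are not column-stochastic, entropy is not bounded by
`ln n`, and difference coefficients can go negative. The default
`paper` mode therefore applies the range step *and then rescales each
column to sum 1* before the entropy `E_j = −(1/ln n) Σ p ln p`; the
`column_share` mode is the textbook normalization (divide by the column
sum). Both modes are exposed because the published near-uniform weights
are consistent with either at low dispersion; at low dispersion the two
differ negligibly.

Degenerate (constant) columns get `E = 1`, `g = 0`, weight 0: zero
dispersion carries zero discriminating information in this method. If
*every* column is degenerate the weights fall back to uniform with a
warning. Natural logarithms throughout; ties in the weight ranking break
by factor code order.

### Mutual-information sensitivity

Plug-in MI from the empirical joint table, in nats (a bits option exists
for reporting). Default discretization is the raw five Likert categories
— the data are already 5-category ordinal, so any further binning only
discards information; an equal-frequency binning utility (ranks split
into `⌈√n⌉` near-equal bins, ties kept together) is available for
continuous covariates or robustness checks.

The **stage-anchored aggregation** defines a factor's sensitivity as its
mean MI with the two primary factors, self-MI counted as 0:
`SV(f) = ½ [I(f;X1) + I(f;X5)]`. The source description of this step is
loose ("the sub-indicators are included in the average"); this rule was
adopted because it is the unique simple aggregation that reproduces the
full published sensitivity row from the published MI matrix for all
eight factors, including the primary factors themselves (which is what
the self-MI = 0 convention is for). Two known discrepancies in the
published text — an SV of 0.2700 vs the table's 0.2800 for X4, and a
swapped 0.1795/0.1757 between X5 and X7 — were resolved in favour of the
tables, which are internally consistent with `OI = SV + w`.

### ETTO optimization

`OI(f) = SV(f) + w_f` (weight as a proportion) balances activity against
risk mass in the spirit of the efficiency–thoroughness trade-off.
Factors are ranked by OI descending (ties by factor code); consecutive
rank pairs (1,2), (3,4), (5,6), (7,8) form four optimization paths from
the better-ranked source to the target, labelled by stage membership
with core = subjective and objective = external poles. The pairing rule
is an interpretation of the published path table and is documented as
such.

## The synthetic panel generator

`simulate_panel()` draws ordinal panels through a Gaussian copula:
latent standard normals with a configured correlation matrix are
thresholded at per-factor cutpoints. The marginal fit parameterizes each
factor's 5-category distribution as a latent normal discretized at
1.5, …, 4.5: the location is solved by 1-D root finding so the discrete
mean matches the target *exactly*, and the scale is optimized so the
discrete SD is as close as the 5-point support allows (a 5-point
distribution cannot realize every (mean, SD) pair — the hard bound
`sd² ≤ (m−1)(5−m)` is enforced, and within it the discretized-normal
family is best-effort, which the stated test tolerances of 0.1 on means
and 0.15 on SDs encode). The correlation matrix's symmetric PSD square
root is used so that a latent correlation of exactly 1 makes two
equal-marginal columns literally identical.

`default_sim_config()` states the study-envelope world: 62 experts;
means spanning 1.79 (X6) to 3.90 (X7) with the remaining six spaced so
the pooled mean is ≈ 2.96, matching the published per-factor extremes
and pooled moments; SDs inside the published 0.90–1.59 range, mostly
near 1 (the pooled SD) with X8 at the upper end so the range is
exercised; latent correlation 0.4 within a stage and 0.2 across stages.
The correlation values are an artifact choice — the original study
reports no correlation structure — so they are configuration, not a
claim about experts.

What the generator does **not** emulate: multi-round elicitation
(consensus feedback would shrink dispersion over rounds), expert
demographics, informative missingness (it produces complete panels
only), and any dependence beyond a Gaussian copula (e.g. tail
dependence in extreme raters). A green test on synthetic data therefore
establishes that the *pipeline computes its quantities correctly under
the stated marginal and correlation structure* — not that the original
study's numbers are recoverable: its posteriors, weights, α, CVI and
ICC depend on the unreleased raw panel and are deliberately not targets.
The desk-reproducible quantities (sensitivity row, optimization indices,
activity sequence, path labels, band calls) are reproduced exactly from
the shipped reference intermediates instead.

## Numerical choices

* **Rounding** for display and for comparing against published
  4-decimal values is half away from zero with a 1e-9 float guard
  (`round_half_away()`); base R's banker's rounding disagrees at exact
  halves (0.05105 → 0.0511, 0.27995 → 0.2800).
* **0·ln 0 = 0** in every entropy/MI sum; MI is clipped at 0 against
  floating-point residue; MI symmetry holds to 1e-12 by computing each
  unordered pair once.
* **Determinism.** The simulator takes an explicit seed, saves and
  restores the caller's RNG state, and identical config + seed gives a
  byte-identical panel CSV. The pipeline itself is seed-free.
* **Ties** always break by factor code order (weights, activity
  sequence), making every ranking total and reproducible.
* **Degenerate inputs** never crash mid-pipeline: constant columns flow
  through QC (flagged), entropy (weight 0, warning) and MI (zero MI with
  everything) to a complete report.

## Known limitations

* The counting denominators, the sensitivity aggregation and the path
  pairing are faithful but interpretive reconstructions of a
  spreadsheet-described method; each is configurable or documented at
  its definition site.
* With n = 62 experts, plug-in MI on a 5×5 joint table has upward bias
  of order (5−1)²/(2n) ≈ 0.13 nats; sensitivity values are comparable
  *within* a panel but not across panel sizes. No bias correction is
  applied, matching the source method.
* The factor-level risk posteriors mix a stage-group prior with a
  secondary-pool likelihood; they are a counting index on [0, 1], not a
  calibrated probability of a real-world loss event.
* Entropy weights collapse toward uniformity whenever expert dispersion
  is low; with 8 near-uniform weights the ranking among them is then
  driven by sampling noise and should not be over-interpreted.
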