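---
title: "Saturation, salience, and domain size in free-list data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation, salience, and domain size in free-list data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freesat)
```

## The data and the questions

A free list is an ordered multi-response answer to an open-ended question:
each respondent names, in order, all the items they can think of in a
topical domain. Three quantities organise the analysis:

* **N** — the number of respondents, in a fixed stored order;
* **L_j** — respondent j's list length, after normalisation;
* **R_ij** — the 1-based rank at which respondent j mentions item i.

The package addresses three questions about such data. When does a series
of interviews stop producing new items (thematic saturation)? How large is
the underlying domain? And — since most studies need the *important* items
rather than all of them — how quickly are the salient items captured?

Respondent order is a contract, not a nuisance. All prefix analyses ("the
first 10 interviews") and the new-item series use the stored order, because
reordering respondents to best fit a saturation curve makes saturation
appear earlier than it is. `permuted_new_item_series()` provides a
permutation-averaged curve as a clearly labelled diagnostic, never as an
input to fitting.

## Normalisation

Hand-collected lists contain case, spacing and spelling variants.
`normalize_label()` case-folds, trims, and collapses whitespace runs, and
then applies an explicit user-supplied synonym map. Nothing fuzzier is
attempted: automatic stemming or distance-based merging would silently
change item counts, and variant merging is a judgement call that belongs in
a reviewable mapping file. Within-list duplicates keep their earliest rank,
which is the rank the salience indices need.

## The saturation model

With respondents in stored order, `new_item_series()` counts the items each
respondent is first to mention. The expected count for the x-th respondent
is modelled as a function of x with four candidate GLMs:

| candidate | family | link |
|---|---|---|
| `nb_log` | negative binomial | log |
| `poisson_log` | Poisson | log |
| `nb_identity` | negative binomial | identity |
| `normal_identity` | normal (OLS) | identity |

Counts of new items are approximately Poisson, but empirical series are
overdispersed — many items are mentioned by only one or two people, so the
curve has a long tail — which the negative binomial absorbs through a
dispersion parameter, estimated by maximum likelihood (`MASS::glm.nb`) with
a moment fallback when ML fails. Model choice is by minimum AIC (with the
dispersion parameter counted), with a deterministic tie-break in the table
order above. Candidates that fail to converge are recorded and skipped; a
fit with a non-significant slope is still usable for prediction, and its
slope p-value is carried alongside.

Saturation is a threshold on the fitted curve: the smallest integer sample
size at which Ŷ(x) ≤ 1 new item per additional person (or ≤ 2 for a more
liberal rule). For a log link the continuous solution is
x = (ln threshold − b₀)/b₁, rounded up. A non-negative slope — or a slope
so close to zero that the solution exceeds 10⁹ — is reported as "saturation
not reached" rather than an error, since flat series are legitimate data.

Two domain sizes derive from the fitted curve. The domain at saturation,
D_SAT = Σ_{x=1..N_SAT} Ŷ(x), sums on the continuous fitted scale without
per-term rounding. The total domain size extrapolates to an infinite
sample: for a log link the yields form a geometric series with ratio
r = e^{b₁} < 1, giving the closed form D_TOT = e^{b₀} r/(1 − r) (the tests
verify it against direct summation of 10⁶ terms to 10⁻⁶ relative
tolerance); for an identity link the descending line is summed with
predictions clamped at zero up to the zero crossing, since a line has no
convergent tail.

## Capture-recapture domain size

The accumulation GLM uses only sample-size increments and ignores both
respondent productivity and item salience differences. The
capture-recapture view uses more of the data: respondents are capture
occasions, items are individuals of a closed population, and the overlap
pattern between lists estimates how many items were never captured. The
sufficient statistic is the capture-frequency spectrum f_j — the number of
items appearing on exactly j of t lists — which satisfies Σf_j = S
(distinct items) and Σ j·f_j = total mentions.

`fit_closed_population()` fits the log-linear (Poisson GLM) form

log E f_j = log C(t, j) + β₀ + β₁ j + β₂ η_j,

where the heterogeneity column η_j encodes the model: absent (M0, the
binomial/homogeneous model), free saturating terms for j ≥ 3 (Chao's lower
bound), 2^j − 1 (Poisson2), j²/2 (Darroch log normal), or
log a − log(a + j) with shape a = 3.5 (gamma; configurable, fixed here as a
conventional default because nothing in the data pins it down). The unseen
count is the j = 0 extrapolation f̂₀ = e^{β₀}, and abundance is S + f̂₀.
Item heterogeneity is, in this setting, exactly heterogeneity in item
salience: a descending concave spectrum with a singleton excess is its
signature.

Numerical choices worth recording:

* η columns are rescaled to unit maximum before fitting — the fit and the
  j = 0 extrapolation are invariant (η(0) = 0), and 2^j − 1 otherwise
  overflows the IRLS weights for t beyond ~30.
* The Chao fit uses rows j ∈ {1, 2} plus a saturated dummy per j ≥ 3 row
  with f_j > 0; zero rows with their own dummy drop out algebraically, and
  excluding them avoids divergent coefficients. The fitted β₀ then equals
  the two-point closed form f̂₀ = f₁²(t−1)/(2 t f₂), which the tests assert.
  Degenerate spectra bypass the GLM: f₁ = 0 gives f̂₀ = 0, and f₂ = 0 uses
  the bias-corrected form f₁(f₁−1)(t−1)/(2t), flagged in the output.
* AIC is computed as 2k − 2·Σ log dpois(f_j, μ̂_j) over the *full* spectrum,
  so models fitted on different row subsets remain comparable.
* Respondent-level (time) variation models are deliberately not part of the
  default pipeline: at the sample sizes involved, item-salience
  heterogeneity dominates, and small-sample screens are the only place
  occasion effects would be identifiable.

`best_domain_estimate()` fits M0 and all four heterogeneity variants and
returns the converged minimum-AIC fit with all candidates attached, since
which variant wins is itself informative (a gamma win signals an extremely
long-tailed domain whose size estimate carries large uncertainty).

The two-respondent estimate n₁·n₂/m (`two_sample_estimate()`) is kept as
the pedagogical entry point to the same logic; with m = 0 it is reported as
undefined rather than silently infinite.

## Salience

Prevalence p = F/N is the simplest salience measure; the Smith and Sutrop
indices add order-of-mention information (formulas above in the README and
in `?salience_table`). The denominator N always counts all respondents in
the (sub)sample, including empty lists, so all measures keep prevalence
semantics. Both rank-weighted indices are bounded by prevalence, with
equality exactly for items always mentioned first — a property the tests
assert on random data, alongside agreement with naive per-item loop
oracles.

`salience_correlations()` reports Spearman and Pearson correlations among
the three measures after filtering to items mentioned at least twice
(singletons carry no order information beyond one list). Aggregation across
examples is an unweighted mean.

The salient-set machinery operationalises "saturation in salience": the
reference set is items at ≥ 20% prevalence among the first 20 full-listing
respondents (both parameters adjustable; 20 respondents because corpora of
interest all reach that size, full listing because it is the more detailed
condition). `capture_proportion()` then measures how much of that reference
is present in the first n (possibly truncated) lists. Capture is monotone
in both n and truncation depth k, which the tests check; the reference set
stays fixed from full lists even when evaluating truncated capture, so the
comparison isolates what limited probing loses.

## The truncation experiment

`truncation_experiment()` composes the pieces: truncate lists to k = 3 (a
typical open-ended question without probing), recompute unique-item yields
at n = 10 and 20, refit saturation on the truncated series, and evaluate
salient capture at the four standard conditions (full lists at n = 10;
truncated at n = 20, 15, 10). The `info_bits` heuristic — mean list length
times sample size — makes the headline mechanism visible: truncation
shrinks the information collected per interview, so saturation arrives
earlier while salient coverage falls. Truncated saturation is *usually*
earlier than full-listing saturation, but not always — a truncated series
can be flatter and fit a shallower slope — so corpus-level summaries use
medians, not per-example inequalities.

## The synthetic generator

`simulate_freelist()` draws each respondent's list length L from a
lognormal (default, sdlog 0.4 — list lengths in listing studies typically
span a 2–4× range within one study) or negative binomial law, clamped to
[1, D], then samples L items without replacement with probability
proportional to fixed salience weights, listing them in sampling order.
Weights default to Zipf, w_i = i^{−s}: a few highly salient items and a
long tail, the shape free-list frequency spectra show in practice. This
makes high-weight items both more prevalent and earlier-mentioned (the
tests check the negative weight–rank correlation), which is all the
analysis assumes — it is a statistical harness, not a cognitive model of
recall, and it deliberately omits semantic clustering within lists,
respondent-level salience differences, and mode effects present in real
interviews. Passing tests therefore demonstrate estimator correctness
under the assumed structure, not robustness to everything real data do.

`simulate_corpus()` fixes the corpus-level defaults once: 28 examples with
N uniform on 20–99, mean list length 6–35, domain size log-uniform on
50–1000, and Zipf exponent 0.7–1.2 — the scales of published listing
studies. `recovery_suite()` runs the bias/RMSE study of both domain-size
estimators over a condition grid; with equal weights the homogeneous model
recovers D within sampling error, and with heavy-tailed weights the
accumulation-GLM total underestimates D while heterogeneity-aware
capture-recapture estimates are larger — the directional pattern that
motivates reporting both.

All randomness is confined to the generator behind explicit integer seeds
(restoring the caller's RNG state); every analysis function is
deterministic, so identical inputs give byte-identical report tables.

## Problem sizes and limitations

The test suite and the acceptance script run entirely on simulated corpora
(28 examples, ~1,100–1,700 interviews total, the size of the motivating
study class) and on small randomised property checks — about a hundred
replicates for the coverage-style assertions — which keeps a full run in
seconds on one CPU while still exercising every estimator end to end.

Known limitations: saturation and domain size are sample-dependent
constructs — an estimate of 73 items does not mean the world contains 73
such items, only that this sample's naming pattern implies a set of that
size; the binomial design calculators assume item independence, which
salience heterogeneity violates, so they are planning floors rather than
guarantees; identity-link negative binomial fits frequently fail to
converge on strongly curved series (recorded, non-fatal); and
capture-recapture standard errors are omitted — the point estimates
already differ across heterogeneity forms by far more than their nominal
errors, and model choice is the dominant uncertainty.
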