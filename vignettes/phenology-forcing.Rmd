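---
title: "Climate extreme indices and phenology forcing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate extreme indices and phenology forcing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoforce)
```

## The problem

Extreme environmental events — heat waves, cold snaps, downpours, failed
rains, droughts, storms — advance or delay crop phenophases (seedling
emergence, silking, grain filling, maturity) even when seasonal means barely
move. `phenoforce` quantifies the *tendency* of an extreme-climate state to
force such shifts. The pipeline has three layers:

1. **Climate extreme index (CEI).** Daily weather is screened for six
   sub-categories of extreme environmental events: high temperature (HT,
   daily maxima), low temperature (LT, daily minima), high precipitation
   (HP), low precipitation (LP), drought duration (D) and wind (W). Each
   sub-index CEI\_X measures how much of the record is extreme; the six are
   combined into one CEI on a 0–100 scale.
2. **Phenology indices.** Observed phenophase shifts, expressed per
   phenophase as a percentage of baseline duration (ΔP), aggregate into the
   phenology shift index `P_Si = ΣΔP / (100 · Np)` and the phenology
   sensitivity `S_CEI = P_Si / CEI`.
3. **Phenology forcing.** `F^p = CEI / S_CEI`, algebraically equal to
   `CEI² · Np · 100 / ΣΔP`. Below a minimum impact limit (MIL, CEI < 1.0)
   forcing is treated as negligible and reported as zero.

## Extreme magnitudes and percentile screening

For a screened variable X (e.g., daily maximum temperature) with reference
mean `X_Avr`, the per-record extreme magnitude is

    E = (X_Avr − X) · X / 100,

the anomaly weighted by the record's own magnitude; wind uses the mirrored
form `E = (WS − WS′) · WS / 100`. E is zero exactly when a record sits at
the reference mean, and screening uses |E|, so the sign convention does not
affect which records count as extreme.

The extreme threshold is the boundary of the most-extreme tenth of |E| over
the *reference* period: with n reference records and screening level p
(default 10 %), the threshold is the k-th largest |E| with
`k = ceiling(n·p/100)`, so exactly k reference records sit at or beyond it
(ties aside). This sort-based convention is deliberately simple enough to be
re-derived independently, and the test suite checks it against a brute-force
oracle.

### Two CEI modes

The deviation-sum form `CEI_X = Σ (E_10p − E_i)/E_i` (with `E_10p` the mean
|E| of the extreme tail) is dimensionally unstable: it is unbounded, blows
up as any |E_i| → 0, and cannot respect a 0–100 scale on which 0 means "no
extreme conditions" and 100 means "the entire record extreme". We therefore
expose two modes:

* **normalized** (default): `CEI_X = 100 · #{records with |E| ≥ threshold} / #records`.
  This is a percent-of-record measure, always in [0, 100], monotone in the
  number of extreme records, and consistent with percent-area CEI semantics.
* **literal**: the deviation sum evaluated verbatim on magnitudes
  (`Σ (e_10p − |E_i|)/|E_i|` over records beyond the threshold, with an
  epsilon guard of 1e-9 on denominators), reported unbounded, for fidelity
  to the printed form.

Aggregation across the six subclasses follows the same logic: the
normalized combined CEI is the *mean* of the six percentages (preserving
the bounds — a plain sum of six quantities each up to 100 could reach 600),
the literal one their sum.

### Precipitation split and drought

One daily precipitation series must feed three indices. We use:

* **dry days** (`precip ≤ dry_threshold`, default 0 mm) belong to the
  drought subclass: monthly dry-day counts DD are screened with
  `E_D = (DD_Avr − DD) · DD / 100` per calendar-month window.
* **wet days** are split at the *reference wet-day median*: above it they
  are screened as high precipitation, at or below it as low precipitation.

Excluding dry days from the HP/LP screening is a deliberate design choice.
With zero-inflated daily rainfall the all-days median can be zero, which
would make the low-precipitation class mostly dry days whose extreme
magnitude is identically zero (E vanishes at X = 0), degenerating the LP
threshold; and dryness is already what the drought subclass measures, so
the split also avoids double counting. A consequence worth knowing:
a day with zero rain contributes to drought, not to "low precipitation" —
LP captures *unusually light rain events*, D captures *absence of rain*.

The paper-style drought categories are driven by full weeks spent under the
longest unbroken dry spell: ≤ 2 near normal, 3–5 mild to moderate, 6–9
severe, ≥ 10 extreme. The category names are standard; the week cutoffs are
package defaults (configurable), since only the category labels, not their
boundaries, are fixed by the drought-duration framing.

### Two-tail note

Each sub-category is described as a sum of a "much above" and a "much
below" percentage. Screening |E| symmetrically subsumes both tails in one
count; a per-side split is not implemented.

## Phenology indices

`delta_p` uses the **absolute** shift (`100·|shift days|/duration`): both
advances and delays count as shift, and a signed sum could go negative,
which would break the sensitivity and forcing algebra (negative S, negative
F^p). The signed shift is retained in the records for reporting.

`P_Si` is read as `ΣΔP / (100 · Np)` — i.e., Np divides. Only this reading
makes the expanded forcing form `CEI²·Np·100/ΣΔP` algebraically identical
to `CEI/S_CEI`; the identity is enforced at run time (1e-9 relative) and
property-tested on 1000 random tuples.

The MIL is inclusive: `F^p(CEI = 1.0) > 0`, `F^p(CEI < 1.0) = 0`. A shift
set with `ΣΔP = 0` under CEI ≥ MIL yields an infinite, *flagged* forcing
rather than an exception, so batch runs survive degenerate rows. The
sensitivity equation applies to the combined CEI and to any single
subclass alike.

Phenophase shift density (PSD) — the fraction of a plant population with a
shifted phenophase — is absorbing by default (a shifted individual stays
shifted within the season, giving nondecreasing curves); a non-absorbing
mode supports curves that plateau and fall.

## The synthetic generators

No usable observational dataset is deposited with the source material, so
the package ships seeded generators that define the study conditions; all
tests and the verification protocol run on them.

**Weather.** The base climate emulates a warm-temperate maize site: daily
minima N(16, 4) °C; maxima N(28, 4) °C, floored at the same day's minimum
plus 0.5; precipitation zero-inflated gamma (wet-day probability 0.6,
shape 2, scale 5 mm — mean wet-day depth 10 mm); wind gamma with mean
15 and sd 5 km/h. These are one-time choices of plausible magnitudes, not
fits to any archive. Extremes are planted by *displacement*: for a subclass
with extreme fraction f > 0, `round(f·n)` records are moved beyond the
reference threshold (solving the quadratic `(X_Avr − X)·X = ∓100·m` for a
target magnitude m 1.3–1.8× the threshold) and the remaining records are,
if necessary, pulled inside it — so the planted fraction, and hence the
normalized CEI_X, is exact by construction. A fraction of exactly 0 leaves
the subclass untouched at its natural ~10 % base rate. Drought planting
converts wet days to dry but always leaves a few wet days per displaced
month, so drought and precipitation extremes can coexist in one series —
this is what lets a single series be 100 % extreme in all six
sub-categories at once.

What the generator does *not* emulate: seasonality, autocorrelation,
cross-variable dependence (hot-dry spells), multi-site correlation, and
instrument error. Passing tests therefore demonstrate the *algorithmic*
properties of the indices (bounds, exact recovery of planted fractions,
threshold conventions), not skill on real station data.

**Phenology.** Ground truth is a sensitivity S\*: the generator inverts
`P_Si = S*·CEI` to `ΣΔP = S*·CEI·100·Np`, splits it equally over the
phenophases and adds independent Gaussian noise (sd in percentage points of
ΔP, truncated at 0). With zero noise the composed recovery of S\* — and of
`F* = CEI/S*` — is exact to 1e-9 relative. Optional per-phenophase caps
(the maize preset: emergence may stretch up to 32 % of its duration,
silking 17 %, terminal stages above 15 %) model biological saturation; caps
break the exact inversion by design and are excluded from recovery tests.

## Verification protocol

The verification procedures are operational definitions chosen by this
package — the summary indices they emulate are described only as curve
shapes in the source material, with no computable procedure, so their
printed values are treated as qualitative shape targets, never numeric
ones.

* **Sensitivity index** at a grid CEI: the percentage of noisy replicate
  shift sets whose forcing index is nonzero and within a relative tolerance
  (default 10 %) of the ground truth `F* = CEI/S*`. With additive ΔP noise
  the signal-to-noise ratio grows with CEI, so the curve rises steeply over
  CEI 1–4 and plateaus near 100 — the documented shape.
* **Uncertainty index**: the bootstrap coefficient of variation of the
  forcing index (mean over resamples of sd/mean). Under the additive-noise
  generator `CV(F^p) ≈ σ/(S*·CEI·100·√Np)`, i.e., ∝ 1/CEI: high at low CEI,
  declining convexly to a stable low plateau. That reproduces the
  "parabolic curvature"/stabilisation shape, but the generator has no
  mechanism by which variance grows faster than the squared mean at high
  CEI, so a terminal uptick of uncertainty at the top of the grid is not
  reproducible under these study conditions, and the tests do not assert
  one.
* **Meta-summary** (forest/funnel): each grid point is one "study" whose
  effect is the mean log-ratio of simulated to true forcing with its
  Monte-Carlo variance. Pooling uses inverse-variance weights
  (fixed-effect) or DerSimonian–Laird random effects (τ² truncated at 0,
  collapsing to fixed when Q ≤ k−1), normal-theory 95 % CIs, and Cochran's
  Q with `I² = max(0, (Q−(k−1))/Q)·100`. The arithmetic is delegated to
  `metafor` and cross-checked against the closed forms in the tests.
  Funnel coordinates are (effect, SE) pairs with pseudo-CI guide lines
  `pooled ± 1.96·SE`.

```{r verify, eval = FALSE}
v <- verify_forcing_model(grid = 1:15, reps = 200, boot = 500, seed = 7)
v$curve
v$meta
plot_verification_curve(v$curve)
```

Default problem sizes — 200 replicates and 500 bootstrap resamples per grid
point, 1–2 year synthetic series (365–730 days), 2000-record series for
recovery checks — were chosen once as the scale at which Monte-Carlo error
is comfortably below the effects being measured.

## Numerical choices and degenerate inputs

* Percentile threshold: sort-based k-th largest with `k = ceiling(n·p/100)`;
  screening uses ≥, so ties at the threshold count as extreme.
* Forcing-form identity asserted at 1e-9 relative on every computation.
* Literal-mode epsilon: 1e-9 on |E| denominators (error, not NaN).
* `CEI = 0` in the sensitivity is an error; `ΣΔP = 0` in the forcing is a
  flagged infinite result; an all-suppressed grid point in the uncertainty
  analysis is `NA`, never a silent 0.
* Reference series defaults to the evaluation series itself when no
  climatology is supplied; then the evaluation cannot be 100 % extreme by
  construction (it defines its own threshold).
* Seeds: every generator and Monte-Carlo routine is a pure function of its
  integer seed; replicate streams are drawn with `sample.int` from a single
  seeded stream, so any sub-computation can be reproduced independently.

## Known limitations

* Single-site daily series only; no gridded or storm-track ingestion.
* The drought index is a dry-day-duration measure, not a water-balance
  model: no soil moisture, evapotranspiration or supply-demand accounting.
* The forcing model is diagnostic, not predictive: it scores observed (or
  simulated) shifts against observed extremity; it does not simulate crop
  development.
* Normalized CEI discards the *magnitude* of exceedance beyond the
  threshold; two records just over and far over the threshold count the
  same. The literal mode retains magnitude but is unbounded and unstable
  near zero anomalies.
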