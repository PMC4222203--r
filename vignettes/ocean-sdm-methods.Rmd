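---
title: "Methods: presence-only maximum-entropy SDM on a synthetic ocean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only maximum-entropy SDM on a synthetic ocean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceansdm)
```

This vignette documents the model, the synthetic world, the numerical
choices, and the design decisions behind `oceansdm` — the things a
maintainer or reviewer would want to know before trusting a green test
suite. It states no empirical result beyond what the test suite and the
demo pipeline themselves compute.

## 1. The maximum-entropy model

Presence-only data tell us where a species was seen, never where it was
absent. The maximum-entropy approach models the *conditional density of
environments at presence sites* relative to the environments available in
the study region. Concretely, with presence covariate rows and a background
sample of the landscape, the raw model is the Gibbs distribution

$$ p(z) = \frac{e^{\eta(z)}}{\sum_{z'} e^{\eta(z')}}, \qquad
   \eta(z) = \sum_j \lambda_j f_j(z), $$

and fitting minimizes the L1-penalized negative log likelihood

$$ J(\lambda) = -\overline{\eta}_{\text{presence}}
   + \log \textstyle\sum_z e^{\eta(z)}
   + \sum_j \beta_j |\lambda_j|. $$

**Normalization set.** The sum over $z$ runs over the background rows
*plus the presence rows*. This mirrors the long-standing default of the
reference MaxEnt implementation ("add samples to background") and is not
merely cosmetic: with hinge features, a linear combination of ramps can
take strictly larger values on every presence than on every row of a
finite background sample (presence values falling into gaps of the
background), in which case the background-only objective is unbounded
below and the weights diverge. Including the presences in the
normalization sum makes $\log Z \ge \overline{\eta}_{\text{presence}}$, so
$J \ge 0$ and a finite optimum always exists. We verified the unbounded
behaviour empirically before adopting this (objective falling linearly
with iteration count, weights growing to $10^5$).

**Features.** Hinge features only, the configuration that matters for
range-edge problems: for each covariate, knots at evenly spaced quantiles
of the combined training values, and per knot a forward ramp
$\max(0,(v-k)/(hi-k))$ and reverse ramp $\max(0,(k-v)/(k-lo))$, scaled to
$[0,1]$ on the training data ($lo,hi$ = combined training min/max).
Degenerate zero-width ramps are skipped; features constant over the
normalization set are dropped (they cannot shape $p$). At projection time
covariates are clamped to $[lo,hi]$, MaxEnt's default clamping;
fade-by-clamping is not implemented. `knots_per_variable` defaults to 30;
the demo pipeline uses 10 for speed (the response shapes saturate well
before that on smooth synthetic fields).

**Penalties.** $\beta_j = b \cdot 0.5 \cdot s_j/\sqrt{m}$, with $b$ the
beta multiplier (default 1, the value used throughout), $s_j$ the feature's
standard deviation over the $m$ presences, floored at $0.001 \times$ the
feature's training range so no penalty is exactly zero.

**Optimizer.** Deterministic cyclic coordinate descent. Each coordinate
takes the exact soft-threshold Newton step
$\lambda_j \leftarrow S(h\lambda_j - g,\ \beta_j)/h$ ($g,h$ = first/second
derivatives of the smooth part), then the *exact* objective change is
evaluated and the step halved until it decreases — so the recorded
regularized gain is non-increasing by construction, even from
near-degenerate curvature. Sweeps stop when the per-sweep gain change drops
below `tol` ($10^{-5}$) *and* every feature satisfies the KKT box condition
$|\overline{f_j}_{\text{presence}} - E_p f_j| \le \beta_j + 10^{-4}$;
`max_iter` (500) is a hard cap, flagged on the model if reached.

**Feature ordering.** Features are sorted once, before the sweeps, by their
gain potential at $\lambda = 0$ (gradient magnitude net of penalty,
descending, ties by index) and cycled in that fixed order. This is the one
place we deviate from naive column-order cycling, and it is deliberate:
percent contributions are computed from per-feature gain increments, and
under collinear covariates (here SST and nitrate are both monotone in
latitude) column-order cycling attributes the shared gain to whichever
variable happens to be enumerated first — we measured contribution splits
flipping from 54/44 to 1/98 purely by reordering columns. The greedy
best-first selection of the reference implementation is what makes its
contribution numbers meaningful; one-shot gain-potential ordering
reproduces that credit assignment while keeping the sweeps deterministic
and cheap.

**Logistic output.** $c\,q/(1+c\,q)$ with $q = e^{\eta - \log Z}$ and
$c = e^{H}$, $H$ the entropy of the fitted raw distribution — the
$\tau = 0.5$ convention: a cell whose raw probability equals the "typical"
value $e^{-H}$ scores exactly 0.5. $\tau$ is exposed but never varied.

## 2. Evaluation

* **AUC** is the rank-based Mann–Whitney estimator with ties counted ½,
  tested against exhaustive pairwise enumeration.
* **Cross-validation** splits the *presences* into k seeded folds; the
  background is shared across folds (the reference tool's convention).
* **Jackknife** refits with each covariate alone and each omitted,
  reporting unpenalized training gain
  $\overline{\eta}_{\text{presence}} - \log Z + \log N_z$ (the improvement
  over the uniform model, in nats).
* **Contributions** are per-variable sums of positive gain increments,
  normalized to 100%.
* **Response curves** vary one covariate over its training range with the
  others held at background means.

## 3. The synthetic ocean: what it emulates, what it does not

The generator reproduces the *structure* of the real inputs — a 1°-class
global climatology and its future-scenario counterparts — not their values:

* masked regular grid, default 2° (1° supported), latitudes −78…80;
  land as smooth random blobs, default 20% of cells;
* SST: zonally symmetric, equatorial ~28 °C to polar ~−1.8 °C through a
  mid-latitude transition (logistic in |lat|, centered 35°, width 10°);
  monthly anomaly $-A\,\mathrm{sign}(lat)\cos(2\pi(m-2)/12)$ with
  amplitude $A$ = 3 °C, so Southern-Hemisphere February is warmest and
  August coldest; floored at −1.9 °C (seawater freezing). Because the
  floor breaks the closed-form monthly mean, the annual layer is *defined*
  as the per-cell mean of the 12 monthly layers, keeping the
  annual/monthly consistency invariant exact;
* nitrate: ~30 µmol L⁻¹ south of a front near 45°S collapsing northward
  over ~4° (logistic in latitude), monotone along every meridian. The
  front *meanders* sinusoidally ±3° with longitude. This meander is a
  deliberate design choice, not decoration: with both SST and nitrate
  purely zonal, hinge features of either variable span the same
  monotone-in-latitude function space and gain attribution between them is
  arbitrary; the meander (a realistic circumpolar-front feature) makes
  nitrate genuinely more informative, which is the stated property of this
  world — the true suitability is driven mainly by nitrate;
* silicate: ≈ 2 × nitrate plus smooth noise, except inside the decoupling
  band (default 50–40°S, the northern range edge) where it is depleted to
  a low, nitrate-independent level — a pure scaling would leave the
  correlation at ~1 and defeat the band's purpose;
* truth: $s = \sigma(\text{nitrate} - 15)\cdot\sigma(7.5 - \text{SST})$
  (slopes 1 L µmol⁻¹ and 1 °C⁻¹) — smooth logistics anchored at the
  species' empirical envelope (nitrate > 15 µmol L⁻¹, SST < 7.5 °C)
  rather than hard thresholds, so parameter recovery is well-posed;
* sampling: records drawn over (cell, month) ∝ truth × month-weight, with
  month weights ∝ $1+\cos(2\pi(m-1)/12)$ — maximal in January, near zero
  in July — mimicking the strong austral-summer bias of high-latitude
  campaigns. The bias *shape* is a modelling choice (no quantitative
  estimate of the real seasonal bias exists); it is exposed in the config;
* futures: each pseudo-GCM warms SST by `delta_sst`·(1+ε) and scales
  nitrate and silicate by `nitrate_scale`·(1+ε′), ε ~ N(0, 0.1) drawn once
  per GCM; salinity unchanged. Defaults 2 °C and 0.8 are a plausible
  end-of-century strong-forcing magnitude for Southern Ocean surface
  waters; they are inputs, not claims.

Not emulated: real coastlines and bathymetry, sea ice, iron limitation,
mixed-layer depth, light, pH, advection by the circumpolar current, or any
real climatology values. A green test therefore establishes that the
*method* recovers a known truth from biased presence-only samples on
WOA-shaped data — it says nothing about how well the method would do on
the real ocean, where covariates are cross-correlated in ways this world
only sketches.

**Background months.** For monthly models the background draw assigns each
point a month uniformly at random and reads that month's covariates, so
the background represents the full seasonal cycle of available
environments while the presences are summer-biased. This asymmetry is what
lets the fitted model reproduce the observed phenomenon that the far-south
range contracts in winter projections: far-south winter cells are common
in the background but rare among presences, so very low SST values are
fitted as low suitability. The alternative — month-matching the background
to the sampling-effort distribution — would cancel the seasonal bias and
with it this signal; we chose the uniform convention and document the
consequence rather than silently baking in either answer.

## 4. Numerical conventions and tie-breaks

* Cell membership: nearest cell center, half-open tie toward +lon/+lat.
* Threshold maps: presence iff suitability ≥ t (cells exactly at the
  cutoff count as presence).
* Consensus count: number of member maps with value ≥ t (default t = 0.2,
  the conventional multi-algorithm comparison cutoff here).
* Ensembles: per-cell mean and *population* SD over GCM members (n = 5
  makes the sample/population distinction material); computed on
  deviations from the first member so identical members give SD exactly 0.
* Boundary profiles: per longitude, the most equatorward latitude of the
  contiguous above-threshold run touching the polar side; masked cells do
  not break a run; detached equatorward patches are ignored (switchable).
* ASCII grids: ESRI header, rows north→south, NODATA −9999, 9 significant
  digits (round trip well under 1e−6). Longitudes are normalized to
  [−180, 180) at read time. NetCDF is declared but unsupported in this
  build (no NetCDF library available); the reader raises a format error.
* Units: canonical °C, PSU, µmol L⁻¹; conversions K→°C and
  mol m⁻³→µmol L⁻¹ (×1000), idempotent.
* Seeds: every stochastic operation takes an explicit seed and draws
  through a local RNG that never disturbs the caller's `.Random.seed`;
  the pipeline derives per-stage seeds from one config seed by fixed
  offsets, so stages are independently reproducible.
* Config: one plain-text JSON file; unknown keys are rejected with
  nearest-key suggestions and *all* violations are reported at once.

## 5. Known limitations

* No numeric agreement with the Java MaxEnt binary is claimed: knot
  placement (quantiles vs data thresholds) and beta flooring details
  differ; agreement is established against the stated objective via an
  exhaustive grid-search oracle instead.
* Only hinge features; no linear/quadratic/product/threshold/categorical
  classes, no cumulative output format.
* The envelope algorithms are documented interpretations (Environmental
  Distance references the presence mean and normalizes by the training
  background's maximum distance, clipped at 0; Bioclim uses the 5–95
  percentile core), not replications of any particular legacy toolbox.
* Regridding assumes rectilinear sources (no curvilinear/tripolar GCM
  grids) and surface layers only; bilinear interpolation does not wrap
  across the dateline.
* Background sampling is without replacement by default (n ≤ ocean cells);
  with a bias grid, zero-bias cells are never drawn and a floor of 1e−6 ×
  max keeps the rest of the ocean admissible.
* The boundary-latitude profile is only meaningful for ranges anchored at
  a pole; fragmented ranges need the non-contiguous variant.
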