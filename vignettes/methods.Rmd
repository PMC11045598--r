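---
title: "Methods: land-cover projection and REDD accounting in reddlcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-cover projection and REDD accounting in reddlcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reddlcm)
```

## Scope and model

`reddlcm` implements the desk workflow behind avoided-deforestation
("REDD") assessments of a forested watershed observed through a series of
categorical land-use/land-cover (LULC) maps:

1. classify per-epoch image stacks into six classes (forest, rangeland,
   cropland, barren land, artificial land, water);
2. cross-tabulate consecutive maps and estimate a first-order Markov chain
   over classes;
3. model *where* conversions happen from biophysical driver surfaces, and
   allocate the Markov demand to the most susceptible pixels;
4. validate simulated maps against observed ones with the Pontius
   agreement statistics;
5. convert projected forest loss in a project area and its leakage belt
   into an annual tCO2e ledger and the net-reduction identity
   `C_REDD = C_Baseline - C_Actual - C_Leakage`.

The Markov model assumes transition probabilities are stationary across
intervals and depend only on the current class (first-order chain); the
potential model assumes drivers are static surfaces. Both assumptions are
exactly satisfiable in the synthetic world and only approximately true of
real landscapes — that gap is the main caveat on what a green test
establishes.

## Conventions and numerical choices

* **Chain orientation.** Transition matrices are row-stochastic,
  `P_ij = n_ij / n_i` with rows = origin class; projection composes by
  right-multiplication, `v(t2) = v(t1) %*% M^k`. A column-stochastic
  formulation is the same chain transposed.
* **Empty origin rows** (`n_i = 0`) are set to identity and flagged with a
  warning, avoiding 0/0 in the estimator.
* **Fractional projection intervals.** Stochastic matrix roots may not
  exist, so a projection over a non-integer number `k` of calibration
  intervals linearly interpolates between the transition-area matrices at
  `floor(k)` and `ceiling(k)` whole powers. This is well defined and
  conservative; it never manufactures transitions absent from both
  endpoints.
* **Demand rounding.** Expected conversions `n_i (M^k)_ij` are rounded to
  integers by largest remainder within each row, so row sums equal the
  current class counts exactly and total pixel count is conserved at every
  stage.
* **Allocation rule.** The calibration software used in published studies
  performs spatial allocation behind closed doors; here it is an explicit,
  testable rule: process ordered transitions by descending demand; for each
  `i -> j`, convert the `demand_ij` still-unconverted pixels of class `i`
  with the highest `i -> j` potential; break ties by ascending column-major
  pixel index. Each pixel converts at most once per projection step.
* **Percentiles and dispersion.** Spectral-temporal metrics use type-7
  (linear-interpolation) percentiles and the sample (n-1) standard
  deviation; both choices are frozen by unit tests (`{1,2,3}` has p25 1.5
  and sd 1).
* **Vegetation indices.** NDVI and DVI from red/NIR; EVI with the standard
  constants G = 2.5, C1 = 6, C2 = 7.5, L = 1 (the index is conventionally
  named without its constants; this is the common Landsat/MODIS
  parameterization). Zero denominators flag the pixel nodata.
* **Train/test split.** Stratified per class; each stratum gets at least
  `floor(n_c * f)` training records and the remaining slots needed to reach
  `round(n * f)` go to the strata with the largest fractional parts. This
  keeps both the global 70/30 contract (800 samples split 560/240) and
  per-stratum proportionality within one record.
* **Pontius decomposition.** With reference proportions `q`, simulated
  proportions `p`, and `J` classes: `NQNL = 1/J`, `MQNL = sum p_j q_j`,
  `MQPL = sum min(p_j, q_j)`, `NQPL = sum min(1/J, q_j)`,
  `PQNL = sum q_j^2`, `PQPL = 1`. The medium-location components
  interpolate linearly in the location skill
  `L = (P0 - MQNL)/(MQPL - MQNL)`: `NQML = NQNL + L (NQPL - NQNL)` and
  `PQML = PQNL + L (PQPL - PQNL)`. When `p = q` the algebra collapses
  `PQML` to `P0`, so `Kquantity = 1` including the 0/0 case, which the
  implementation resolves to 1 when `P0 = NQML` and flags `NA` otherwise.
  Degenerate marginals (`MQPL = MQNL`) give `L = 1` iff `P0` attains the
  ceiling. These formulas are frozen against an independent direct-counting
  oracle over every pair of 2x2 maps on 3 classes.

## The classifier and the potential model

No tree-ensemble or neural-network package is assumed: both learners are
part of the package and unit-tested.

* The land-cover classifier is a bagged CART forest (Gini impurity,
  bootstrap per tree, per-node random feature subsets of size
  `floor(sqrt(p))`, majority vote), with ensemble size the only exposed
  hyperparameter (default 500 trees, the value used operationally in this
  literature); depth/node-size defaults are recorded in the model object.
* The transition-potential model is a single-hidden-layer perceptron with
  logistic activations, hidden width `max(4, n_drivers)` — the smallest
  standard topology, since only the stopping criteria (RMS 0.01, 1000
  iterations) are conventionally reported. It minimises MSE with Adam on
  standardized drivers, balanced changed/persistent samples (equal draws
  per label, capped at 4000 each), and an internal 70/30 split whose
  training and testing RMSE are both reported. One potential surface is
  fitted per off-diagonal transition with positive demand (the per-
  transition alternative to a single joint model; transitions whose
  calibration labels are single-class fall back to a uniform surface).

## The synthetic world

The generator emulates a temperate mountain watershed observed at 30 m for
seven epochs (1985-2020):

* **Initial map**: one smoothed Gaussian noise field (separable box blur,
  three passes) thresholded at cumulative class-prevalence quantiles —
  contiguous patches with exact prevalences (default 45% forest, 25%
  rangeland, 12% cropland, 10% barren, 5% artificial, 3% water; chosen as
  a plausible forested-watershed composition, since no numeric prevalences
  are published for such sites beyond forest area).
* **Dynamics**: one row-stochastic matrix per interval; the default series
  has three deforestation intervals followed by three recovery intervals,
  reproducing the decline-then-recovery pattern reported for protected
  Caspian-belt forests. Per-pixel class draws use the Gumbel-max trick on
  the row log-odds, additively tilted by standardized driver values times
  per-destination effect weights; all-zero weights recover the pure Markov
  kernel *exactly*, which is what makes parameter-recovery tests sharp.
* **Drivers**: elevation (432-3800 m, the altitude span typical of the
  emulated study region) and distance-to-road (0-5 km), both smoothed
  random fields; conversion to cropland/artificial is favoured at low
  elevation and near roads (weight -1.5 per sd), reversion to forest away
  from them (+0.75).
* **Burn-in**: the landscape is evolved for two unrecorded intervals under
  the first matrix before epoch 1, so the observed series starts near the
  regime's quasi-equilibrium rather than in the transient of the
  thresholded initial map. Without this, the calibration interval
  overstates change and biases the Markov demand for later intervals.
* **Imagery**: per-class six-band reflectance signatures with independent
  Gaussian noise (sd 0.015) per band and scene; 10-28 scenes per epoch
  spread across an April-September growing season. No atmosphere, clouds,
  or geolocation error.
* **Seeding**: one integer seed fans out to per-operation substreams via
  `(seed * 16807 + op_id) mod (2^31 - 1)` with documented op ids, so every
  artifact is bit-reproducible and operations are independently
  re-runnable.

### Calibrating the default world, and what it cannot do

Two published features constrain the defaults: per-interval forest change
rates in the single-digit-percent range, and projection agreement
(`Klocation`, `Kquantity`) in the mid-0.9s for a well-calibrated model.
Because the generator draws conversions *independently per pixel* given the
drivers, these two features trade off through the gross change rate: the
location information a model can possibly recover is bounded, and
measurement with an oracle ranker (the generator's own conversion
probabilities) showed the MLP allocation sits essentially at that ceiling.
The shipped defaults (persistence about 0.98 per interval, driver weight
1.5 sd, burn-in 2) satisfy both regimes — realized forest rates of roughly
-3% to +3% per interval and `Klocation` about 0.94 / `Kquantity` about
0.98 on the calibrate-then-forecast protocol. What the generator does *not*
emulate: spatially contiguous change patches (real deforestation fronts),
classification error in the observed maps, nonstationary drivers, and the
extreme single-interval loss rates a real episode can show. A green
end-to-end test therefore establishes that the pipeline recovers a world
that satisfies its own assumptions — not that any real landscape does.

## REDD accounting choices

* **Emission factor**: default 10 tCO2e per deforested hectare. This is a
  reporting convention that reproduces the headline arithmetic of the case
  study the package emulates (about 2.0 MtCO2e from about 0.2 Mha); no
  carbon density is published there. Real accounting should substitute a
  biome-appropriate factor — the ledger is linear in it.
* **Annualization** between projection epochs is linear in hectares, the
  simplest rule consistent with period-average reporting; the final
  observed rate is carried forward when the horizon outruns the last mask.
* **Sign convention**: the ledger reports *signed* net-change emissions;
  net forest recovery yields negative deforestation and negative emissions
  (sequestration) rather than a separate sequestration series with an
  opaque sign.
* **Scenario terms**: effectiveness `e` removes a fraction of baseline
  deforestation in the project area (`actual = (1 - e) baseline`);
  displacement `d` routes a fraction of the avoided deforestation into the
  leakage belt (`leakage = d e baseline`). With `e = 0, d = 0` the
  with-project ledger equals the baseline exactly, and
  `C_REDD = C_Baseline - C_Actual - C_Leakage` holds to the last unit on
  every fixture by construction (it is computed, not accumulated).
* **Leakage belt**: an input mask, or a pixel-dilation buffer of
  configurable width around the project area; no belt width is
  conventionally standardized.

## Known limitations

* No cellular-automaton neighbourhood term: spatial allocation uses driver
  surfaces only, so projected change lacks patch-growing behaviour.
* The chain is first-order and stationary per calibration interval;
  regime shifts (decline to recovery) are handled only by choosing the
  calibration pair.
* Rasters are in-memory matrices serialized as text ASCII grids — suitable
  for watershed-scale grids, not out-of-core national mosaics, and no map
  projection metadata is carried.
* Accuracy assessment treats reference samples as error-free.

## Reproducing the numbers

Every empirical figure quoted above is computed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) or by
`scripts/acceptance.R`; the vignette states no result they do not compute.
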