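---
title: "Methods: from sea-level proxies to landscape and cultural indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sea-level proxies to landscape and cultural indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
set.seed(1)
```

`paleoscape` implements the quantitative chain used to study how a
low-gradient island landscape and its inhabitants respond to gradual
sea-level rise: proxy samples are converted to sea-level index points
(SLIPs), a probabilistic sea-level curve with rates is fitted, candidate
glacial-isostatic-adjustment (GIA) histories are ranked against the
index points, a raster inundation model turns sea-level histories into
land- and intertidal-area series and fragmentation counts, and two
cultural proxies — radiocarbon summed probability distributions (SPDs)
and aoristic monument sums — together with pollen/charcoal indices track
the human and ecological response.  Everything is driven by a
synthetic-data generator with known ground truth, so each stage can be
tested end to end without field data.

Ages are everywhere in calendar years (or ka) before 1950 CE, increasing
into the past.  Rates of sea-level change are mm per calendar year,
positive when the sea rises toward the present.

```{r setup}
library(paleoscape)
```

## What the synthetic generator emulates

`scilly_like_truth()` fixes the study conditions.  Its rate history is a
piecewise-linear curve anchored so that the integral reproduces the
headline numbers of the reconstruction the package is built around:
a mean rise of 2.8 mm/yr between 7 and 4.5 ka, 2.8 mm/yr at 5 ka,
1.1 mm/yr at 4 ka, a mean of 0.8 mm/yr from 4 ka to the present, and a
rapid (6–10 mm/yr) Early Holocene rise.  The level history is the exact
piecewise-quadratic integral of that rate, pinned to 0 m at present.

```{r truth}
truth <- scilly_like_truth()
truth
curve(truth$rsl_truth(x), 0, 9, xlim = c(9, 0),
      xlab = "Age (ka BP)", ylab = "RSL (m)")
```

`sample_slips()` draws dated elevations from this curve with independent
Gaussian age and elevation errors and, optionally, limiting points
displaced half-normally to the correct side of the curve (marine
limiting below, terrestrial limiting above).  The default acceptance
configuration uses 70 points of which about 22 are precise — the size
and composition of a realistic Holocene island database.  Real SLIP
errors are partly shared between samples (surveying benchmarks,
transfer-function calibration); the generator treats them as
independent, so passing tests demonstrate correct behaviour under the
stated error model, not robustness to correlated errors.

The DEM generator (`make_dem()`) builds parametric islands.  The default
`archipelago` shape is a broad shelf dome of gradient 0.002 m/m crowned
by five steep peaks: because the shelf is nearly flat, a metre of
sea-level change sweeps the shoreline hundreds of metres, producing the
nonlinear area response and eventual fragmentation that motivate the
whole analysis.  Plate, plane, cone and paraboloid shapes exist because
their hypsometry is analytic, which gives the area computations an
independent oracle.

Radiocarbon datasets are drawn by inverse-CDF sampling of a population
curve followed by perturbation through a synthetic IntCal-style
calibration curve; monument inventories mix period windows of different
widths with an "unknown age" fraction; pollen counts are multinomial
along a latent ecological gradient with exactly 300 land-derived grains
per sample, optionally with a halophyte-dominated block emulating salt
marsh.  All generators are pure functions of their parameters and a
seed, with per-operation substreams (`substream_seed()`) so that adding
a call never shifts another call's stream.

## Sea level

**Transfer function.** `fit_wapls()` implements weighted-averaging
partial least squares with inverse deshrinking.  Components are
extracted by iterated weighted averaging of the regression residuals;
the final weighted regression of observed elevation on component scores
is the deshrinking step.  With one component the model is classical
weighted averaging, which the tests exploit as a closed-form oracle.
Training and fossil assemblages must exceed 50 counted tests — the usual
screening threshold below which assemblage proportions are too noisy —
and the prediction error is a bootstrap RMSEP.  Two components are the
default, matching common practice for single-gradient intertidal
training sets.

**Index points.** `build_slip()` applies `S = H − I`: sample elevation
minus the indicative meaning (the height of the depositional environment
above former sea level, e.g. the transfer-function paleomarsh surface
elevation).  The 2σ vertical error is twice the root-sum-of-squares of
the 1σ surveying, sampling and transfer-function components.
`tidal_standardize()` rescales heights above MSL by the spring-range
ratio when moving between tidal frames (training estuary to study site).

**EIV-IGP.** `fit_eiv_igp()` is the probabilistic curve.  The *rate* of
sea-level change is the latent process — a scalar mean rate plus a
zero-mean Gaussian process with squared-exponential covariance on ~25
knots — and the level is its exact integral, so rate and level
posteriors are consistent by construction (the integrated-GP
construction).  Observed elevations are Gaussian about the level at a
latent true age; latent ages get Gaussian priors centred on the observed
ages (errors-in-variables), which matters because a dating error on a
steep part of the curve masquerades as a large elevation error.
Sampling alternates elliptical slice sampling of the whitened rate
field — with the two linear nuisance parameters (level offset, mean
rate) marginalized out by a rank-2 Woodbury identity, which removes the
worst posterior correlations — a conjugate draw of those two parameters,
per-point Metropolis updates of latent ages, and Metropolis updates of
the GP amplitude and length-scale under half-normal priors (scales:
5 mm/yr; half the data span).  Vertical errors enter as the 2σ table
column halved; a 0.01 m floor keeps noise-free synthetic data usable.
Chains default to 3000 iterations (1000 burn-in); a split-chain R-hat
above 1.15 on the offset and mean rate raises a warning rather than
being swallowed.  Grid points outside the data span are returned only
with an explicit `extrapolated` flag.

Two properties are worth knowing.  First, interval-averaged rates
(`mean_rate()`) are recovered nearly unbiasedly, but *pointwise* rates
near a sharp change in slope are smoothed: with ~22 precise points the
fitted rate at the foot of a steep-to-gentle transition lands between
the two regimes.  Second, simulation shows the 95% level band covers the
generating truth at roughly its nominal rate (the test suite checks
≥ 90% coverage over 20 replicates).

**GIA ranking.** `score_chi2()` computes the reduced misfit
χ² = 1/(N−1) Σ ((RSLᵖᵢ − RSLᵒᵇˢᵢ)/σᵢ)² with σᵢ the 2σ observational
errors, candidates linearly interpolated at SLIP ages and limiting
points excluded; `select_gia()` sorts candidates ascending with
lexicographic tie-break.  Candidate curves are inputs — no forward GIA
modelling is attempted.

## Paleogeography

`water_levels()` reduces a tidal epoch to spring levels: MHWS is taken
as the sum of the M2 and S2 amplitudes about contemporaneous MSL and
MLWS as its negative.  The constituent combination is exposed as a
function argument because other conventions (adding further
constituents, shallow-water corrections) are defensible.
`reconstruct()` classifies every DEM cell: land above MHWS, intertidal
in (MLWS, MHWS] — a cell exactly at MHWS is intertidal — and subtidal
below; nodata cells belong to no class, and the per-epoch bookkeeping
(`n_land + n_intertidal + n_subtidal + n_nodata = total`) makes that
choice auditable.  Island counting is connected-component labelling of
the land mask, 8-connectivity by default so that diagonally touching
land is one island (conservative against spurious fragmentation), with
an optional minimum component size.

`area_series()` sweeps a sea-level history (any `(time, RSL)` table —
posterior mean, a credible bound, or a GIA output; curve choice is the
caller's) against tidal amplitudes interpolated to the same epochs, and
derives the land/intertidal ratio and the intertidal percentage of the
area above MLWS.  `change_metrics()` rescales each between-epoch change
linearly to a human window (a 70-year lifespan, a decade), in m² and as
a percentage of the start-of-interval area; `lateral_rate()` finds the
MHWS shoreline along a transect by linear interpolation of
`elevation − rsl − MHWS`, so a vertical cliff yields a near-zero lateral
rate no matter the rise.

```{r paleogeo}
dem <- make_dem(default_island_shape(), cell_size = 100, seed = 1)
rsl <- data.frame(time_ka = 0:8, rsl_m = truth$rsl_truth(0:8))
ser <- area_series(dem, rsl, make_tide_history(0:9))
ser[, c("time_ka", "land_km2", "intertidal_km2", "island_count")]
```

## Demography

`calibrate()` evaluates the Gaussian likelihood of a radiocarbon age
against the calibration curve on its calendar grid; SPDs sum
*unnormalized* densities, the convention that avoids artefacts from
normalizing multimodal densities before summation.  To stop
heavily-sampled phases dominating, `bin_dates()` clusters same-site
dates on sorted uncalibrated age, opening a new bin when a date is more
than 50 yr from the current bin's first member — deterministic and
order-independent, though other implementations anchor bins differently
and can split edge cases into different bins — and `spd()` averages
member densities within a bin before summing bins.

`permutation_test()` holds the pooled dates fixed and reassigns region
labels at random (region sizes preserved), yielding a pointwise 95%
envelope of "no regional difference" SPDs; observed values outside it
are flagged as positive or negative departures.  The envelope is
pointwise, not simultaneous — it mirrors critical-threshold shading, and
the family-wise error across grid points is correspondingly larger than
5%.  Envelopes are computed on raw SPDs by default, with an optional
rolling-mean pre-smoother (`smooth_halfwidth`) because smoothing before
thresholding is equally defensible and sharpens block contrasts.

`aoristic_sum()` spreads each known-age monument's unit mass uniformly
over its period window and sums per 200-yr bin, so imprecisely dated
records are automatically downweighted per bin; unknown-age records are
screened out first, zero-length windows become a point mass in their
containing bin, and total mass equals the number of usable records to
10⁻⁹.

## Vegetation and fire

Pollen percentages (on the land-taxon sum) are clustered by Ward's
criterion (`hclust` `ward.D2`) on Bray–Curtis dissimilarities — the
community-ecology default, with Euclidean available; the number of
clusters, when not given, maximizes mean silhouette over k = 2…8.
`phytosociology()` tabulates, per cluster and taxon, the occurrence
frequency and a class on even 20% cutoffs (class 5 = present in 81–100%
of samples) plus mean, median and IQR of the percentages.
`screen_halophytes()` drops every sample of any cluster whose listed
halophyte (e.g. a Chenopodiaceae-type taxon) reaches class 4 by default
— those assemblages record salt-marsh proximity, not land cover.
Screening happens before ordination: a land-cover index should not let
salt-marsh samples shape the ordination space it is read from.

`nmds()` wraps `vegan::metaMDS` (Kruskal stress-1, Bray–Curtis, no
autotransform, seeded restarts); `veg_index_trend()` smooths axis-1
scores against age with a penalized cubic regression spline
(`mgcv::gam`, GCV-selected penalty) and reports pointwise standard
errors on a regular grid.

`charcoal_composite()` applies the standard record-compositing protocol
in order: concentration values times sedimentation rate give influx;
a Box–Cox transform (λ by profile likelihood on values shifted by half
the smallest nonzero value) homogenizes variance; min-max rescaling to
[0, 1] puts sites on one scale; z-scoring against a fixed 200-yr-class
base period centres them.  The base-period window location is a required
argument — it is an analytic choice that changes the meaning of the
z-scores, so no default is imposed.  Records are then smoothed with a
300-yr half-width window onto a common 100-yr grid and averaged, with a
bootstrap-over-records band.  Zero-variance records cannot be z-scored
and are excluded with a warning.

## Pipeline

`run_pipeline()` wires the stages together through CSV/ASCII-grid files
in a run directory, with per-stage content-hash caching (parameters plus
input checksums) and a YAML manifest recording the config hash, package
version, output checksums and timings.  Unknown configuration keys are
rejected before anything runs, and a missing input fails naming the
offending path.  `demo_config()` builds a complete synthetic run;
`inst/scripts/paleoscape` is a thin shell wrapper over these two
functions.

## Numerical choices and problem sizes

Defaults were fixed once, at scales a desk analysis of a single island
warrants: 100-cell sea-level grids and 25 GP knots; 3000-iteration
chains (the diagnostics flag, rather than hide, anything shorter that
fails to mix); 1000 permutations for production SPD tests and 200 in the
simulation studies; 20 replicates for coverage and type-I calibration;
50-sample, 300-grain pollen sets.  The acceptance script's sea-level
stage uses 70 index points (~22 precise) and a 5000-iteration chain.

## Limitations

The generator's independence assumptions (uncorrelated SLIP errors,
site-independent dates), the pointwise (not simultaneous) permutation
envelope, the corner-smoothing of pointwise GP rates, planar geometry
with no map projection, and the absence of sediment dynamics or erosion
all mean that green tests certify the computational chain under its
stated model, not the full messiness of field data.  Marine reservoir
corrections, date-quality screening heuristics and Bayesian growth
models are deliberately out of scope.
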