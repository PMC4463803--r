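---
title: "Trait sensitivity analysis of a reduced-order wheat simulator: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait sensitivity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the reduced-order crop model and its assumptions, the synthetic weather
that drives it, the two global sensitivity methods, the numerical and
design choices that were genuinely open, and what the passing tests do and
do not show about real wheat.

## The question

Grain yield (GY) and grain protein concentration (GPC) are negatively
correlated across wheat genotypes, and both emerge from many interacting
morpho-physiological traits. Treating the 75 parameters of a process-based
wheat simulator as "traits" and perturbing each within ±20 % of its
nominal value (the range of observed genetic variation for most of them)
turns trait prioritization into a global sensitivity analysis: which
parameters move GY, GPC, and grain protein deviation (GPD, the residual of
GPC regressed on GY across perturbed genotypes), and how stable is the
ranking across climates, N supplies, and weather years?

## The simulator

One call to `run_season()` integrates a crop from sowing to physiological
maturity on a daily time step. The state comprises soil water and mineral
N, thermal-time phenology, a stack of leaf layers, carbon and N pools per
organ, and the grain. A compiled core (`src/season.cpp`) mirrors the
documented R step functions one operation at a time; the test suite
asserts the two engines equal over random parameter draws, so the R
functions remain the authoritative definition.

### Phenology

Thermal time accumulates as `max(0, T)` (base 0 °C, the standard
convention for wheat). The phyllochron clock advances by
`tt / (P · f)` with `f = Pdecr` below leaf `Ldecr`, `Pincr` above
`Lincr`, 1 between. Vernalization progresses at
`VBEE + VAI·T` between 0 °C and `IntTvern`, declining linearly to zero at
`MaxTvern`. The final leaf number interpolates from `MaxL` toward `MinL`
with the vernalization effect and adds a short-day term
`SLDL · (16 − daylength)`, clipped to `[MinL, MaxL]`. Two choices here
were genuinely open, because the original daylength/vernalization
subroutines are external to the source text:

* the vernalization effect is the progress achieved when the Haun index
  reaches 4 (a floral-initiation reference window), evaluated once
  vernalization completes — this keeps all four vernalization parameters
  live with the right monotonicities;
* the 16 h reference daylength represents long-day saturation.

Emergence occurs `Dse` °Cd after sowing; flag-leaf ligule when the Haun
index reaches the final leaf number; anthesis `PFLLAnth` phyllochrons
later; the grain phases end `Dcd`, `Dcd + Der` and `Dgf` °Cd after
anthesis. While the canopy is shorter than `MaxLeafSoil` leaves, canopy
temperature is a 5-day trailing mean of air temperature (a stand-in for
soil temperature; no soil-temperature model is in scope).

### Canopy

The canopy is `ceil(FLN)` leaf layers per shoot at a fixed density of
500 ear-bearing shoots m⁻² (2 shoots × 250 plants; tillering dynamics are
outside the parameter set). Pre-floral layers carry `AreaSL` laminae and
`AreaSS` sheaths; the `NLL` culm layers ramp linearly to `AreaPL` at the
penultimate rank, the flag leaf is `RatioFLPL · AreaPL`, and culm sheaths
follow `AreaSS · (1 + aSheath · (j/NLL)²)` — the quadratic form in culm
rank is this package's concrete reading of a relationship whose exact
form is unpublished. A fractional `NLL` weights the earliest culm layer
between the two geometries.

Each layer expands linearly over `PexpL` phyllochrons, scaled by the
drought expansion factor (FTSW ramp between `LowerFTSWexp` and
`UpperFTSWexp`) and capped by the lamina area the day's N supply can
furnish at the critical specific leaf N (`CritSLN`). Expansion is
development-driven, not carbon-driven: the dry-matter cost (at the target
specific weights `SLWp`, `SSWp`) is booked afterwards from the day's
production, a 10 g m⁻² seed reserve, and the stem's labile carbohydrate
pool, in that order; under source limitation leaves simply run below
their target specific weight. An earlier draft carbon-gated the area
itself; that starved cool-site canopies, inverted the phenology–yield
effect directions, and was removed — the change is visible in the test
suite as healthier green area indices (5–6 under high N) and is the
design the source model's structure implies. After a lag of `PlagLL`
(culm) or `PlagSL` (pre-floral) phyllochrons each layer senesces over
`PsenLL`/`PsenSL` phyllochrons, accelerated up to `MaxDSF`-fold as FTSW
falls from `UpperFTSWsen` to `LowerFTSWsen`.

### Biomass and its five modifiers

`dDM = RUE · fT · fCO2 · fN · fR · fW · iPAR`, with
`iPAR = 0.5 · srad · (1 − exp(−Kl · GAI))` from the previous day's canopy.
`fT` is piecewise linear (0 at 0 °C, 1 at `Topt`, 0 at `Tmax`);
`fCO2 = 1 + FacCO2 · ln(CO2/350)`; `fN` saturates exponentially in mean
green-lamina specific N between `MinSLN` and `MaxSLN` with rate `TauSLN`;
`fR = (1 + SlopeFR · fdif)/(1 + SlopeFR)` equals 1 under fully diffuse
(overcast) light, with the diffuse fraction tied to the generator's
wet/dry state (1.0 wet, 0.5 dry); `fW` is the FTSW ramp between
`LowerFTSWrue` and `UpperFTSWrue`. Scenario CO₂ is fixed at 360 ppm, the
ambient mid-point of a 1970–2009 window, so the CO₂ sensitivity is a live
(if small) factor.

### Nitrogen

Crop N demand is capacity-driven. The critical dilution curve
`%N_crit = AlphaNNI · DM_t^(−BetaNNI)` (DM in t ha⁻¹, constant below
1 t ha⁻¹) defines the N nutrition index NNI. The lamina capacity
integrates an exponential vertical N profile over relative canopy depth
whose N-to-light extinction ratio is `AlphaKn · NNI^BetaKn`: a well-fed
crop concentrates N at the top and the per-area capacity self-limits.
This orientation (capacity falls as NNI rises) is the published
relationship and is numerically stabilizing; the opposite orientation
makes the N-allocation scaling parameters implausibly dominant. Sheath N
follows the lamina allometry (`AlphaSSN`, `BetaSSN`); stem+ear capacity
is `MaxStemN` per unit DM. Daily uptake is the minimum of demand, soil
mineral N, and `MaxNuptake · min(1, DM/DMmaxNuptake)`, declining linearly
with thermal time after anthesis to zero at `Dgf`. Structural N
(`StrucLeafN`, `StrucStemN`) is non-remobilizable and leaves with
senescing tissue.

### Grain

At anthesis the grain number is `EarGR` per gram of ear DM (the ear grows
during a window opening `Deg · PFLLAnth · P` °Cd after flag-leaf ligule,
taking `FracBEAR` of post-leaf assimilate). During the cell-division
phase structural grain DM grows exponentially at `Kcd` per °Cd from a
0.1 mg-per-grain seed mass, with structural N in the fixed ratio
`AlphaNC`; surplus assimilate in this phase banks as labile stem
carbohydrate. Afterwards all new biomass goes to the grain together with
a reserve pool released linearly until `Dgf`. The reserve combines
`FracLaminaBGR`/`FracSheathBGR` of the *anthesis* lamina/sheath DM (the
parameter definitions) with the labile stem carbohydrate held at the
*end of cell division* (the process description); the two source
statements disagree on the reference date and this split honours both.
Grain N transfer is first-order in the labile lamina and stem+sheath N
pools (`MaxLeafRRND`, `MaxStemRRND` per °Cd), tapering linearly to zero
between the end of endoreduplication and maturity; lamina N withdrawal
senesces green area through the `LLOSS` coupling. GPC is
`100 · 5.7 · grainN / grainDM` (the standard wheat N-to-protein factor;
not stated in the source).

### Soil

A single root-tracking bucket: transpirable capacity is
`awc · root_depth / max_root_depth`, roots extend at `RVER` m per °Cd,
and newly rooted soil arrives at the current wetness fraction. Reference
evapotranspiration is Hargreaves (no humidity or wind inputs needed),
partitioned by canopy cover; soil evaporation shuts down linearly below
FTSW 1/3. Transpiration is demand times the stomatal FTSW ramp, capped by
a root extraction limit `w · MaxRWU · (1 − exp(−10 · BetaRWU · depth
fraction))` — the top-layer maximum relative rate discounted by the
profile-extraction efficiency. A fraction `percolation_coeff` of
above-capacity water drains each day; leaching removes
`min(1, drainage/awc)` of the mineral pool; mineralization is first-order
in organic N with a linear 0–20 °C temperature factor (the simplest form
that keeps the published constant interpretable). Water, carbon, and N
ledgers close to better than 10⁻⁶ relative over any season — this is
asserted over a thousand random parameter draws.

## Synthetic weather

The generator is a stand-in for forty years of station records that are
not redistributable: daily mean temperature is a site sinusoid (warmest
day 20 July) plus an AR(1) anomaly (coefficient 0.6, a typical
mid-latitude persistence); precipitation occurrence is a seasonal
two-state Markov chain with gamma amounts; radiation is the
extraterrestrial envelope times 0.75 transmissivity times 0.75 (dry) or
0.35 (wet) cloudiness, which supplies the rain–radiation anticorrelation
the drought analysis needs. Presets for the three sites were calibrated
once so that, with nominal crop parameters, the emergence–anthesis and
anthesis–maturity window statistics approach the published site medians
(e.g. 9.0 °C pre-anthesis at AV — reproduced at 9.4 °C; ~446 mm
pre-anthesis precipitation at RR — ~478 mm; anthesis medians within about
a week of 11 May / 26 May / 11 June). Each calendar year draws from its
own derived RNG substream, so year k is invariant to series length. What
the generator does *not* emulate: spell-length clustering beyond first
order, interannual trends, heat waves uncorrelated with drought, and
humidity/wind (hence Hargreaves rather than Penman ET). Passing tests on
this weather show the analysis machinery behaves correctly and the
qualitative climate contrasts are right; they do not validate the
simulator against field observations.

## Sensitivity methods

**Morris screening.** `sample_trajectories()` builds r = 10 trajectories
of k+1 points on an 8-level grid with `delta = p/(2(p−1)) = 4/7`; every
factor moves exactly once per trajectory, giving 760 parameter vectors
for k = 75. Elementary effects are signed finite differences on the
unit-cube scale, so `mu*` is comparable across parameters with different
units; `sigma` flags non-linearity/interaction. Per output, site, and N
treatment, medians over years are min–max rescaled to [0, 1] pooled
across sites and treatments, and signed by the slope of an independent
one-at-a-time sweep (multipliers 0.5–1.5 of nominal). Incomplete seasons
drop their whole trajectory to keep effect pairing intact. The sampled
statistics are tested against brute-force enumeration of every admissible
elementary effect on the full grid (k ≤ 3); because the sigma estimator's
sampling noise at r = 200 is itself about 5 % of sigma, that test
averages the estimator over four fixed designs rather than loosening the
band.

**Extended FAST.** Each factor in turn is driven at
`omega_max = floor((ns−1)/(2M))` along an arcsine search curve while the
others sit at low complementary frequencies; `S_i` is the spectral power
at the driven frequency and its first M = 4 harmonics over the total
variance, `S_Ti` is one minus the low-frequency (complementary) share.
With the classic single curve per factor the complementary frequencies
are few and commensurate, and their interaction variance along one curve
is phase-dependent; the design therefore randomizes complementary
frequencies and phases per curve and can average `resamples` independent
curves per factor. The estimator is validated against the closed-form
Sobol decomposition of the Ishigami function (within ±0.05 at ns = 729)
and obeys `0 ≤ S_i ≤ S_Ti ≤ 1` universally. The influential-factor rule
(factors covering 90 % of the summed `S_Ti` in at least half the years of
at least one site × N cell) is implemented in `select_influential()`.

## Problem sizes and what the results show

The acceptance suite runs the full screening matrix at 10 synthetic
years × 3 sites × 2 N treatments (45 600 season runs), the one-at-a-time
sign sweeps over 2 years, and the variance-based analysis at the method's
minimum curve length (ns = 65) with 3 resample curves over 3 years under
high N — sizes chosen so the whole suite completes in minutes on one CPU
while preserving the year-uncertainty structure. At these conditions:
RUE attains the top median `mu*` for grain yield under high N at all
three sites (a robust result across seeds); more than 80 % of
factor-scenario pairs influential on both GY and GPC push them in
opposite directions; high-N yields exceed low-N yields and the Oceanic
site out-yields the Mediterranean one; and the GPD slope is negative in
most low-N scenario-years. The E-FAST top rank for GY at the wet sites is
seed-sensitive at desk scale: across weather draws it trades between RUE
and the phyllochron — an instability worth noting because the full-scale
source analysis itself reports the phyllochron leading at the wettest
site in the variance-based ranking while the screening ranking puts RUE
first everywhere.

## Known limitations

* The simulator is reduced-order: one soil bucket, no tillering, no
  per-layer photosynthesis, no floret abortion, no Penman ET, fixed shoot
  density. Absolute yields (0.35–0.65 kg DM m⁻² medians) and the ~30 %
  high-vs-low-N yield gap are in the right range but muted relative to a
  full multi-layer model; directions and rankings, not magnitudes, are
  the deliverable.
* `LowerFTSWrue` has nominal value 0, so the multiplicative ±20 %
  perturbation rule cannot move it; its code path is exercised with an
  absolute probe in the tests.
* Two aggregate parameter orderings (`Dcd + Der ≤ Dgf`,
  `CritSLN ≤ MaxSLN`) can be violated by independent ±20 % draws;
  validation is advisory and the simulator clips exactly these two where
  physically required (the grain-N taper window and the specific-leaf-N
  ceiling).
* GPD is computed within each design sample (per scenario-year across
  perturbed genotypes), so its regression slope and r² depend on the
  design's spread; values are reported, not calibrated.
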