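---
title: "Modelling a multi-species functional response from strandings, telemetry and trawl surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a multi-species functional response from strandings, telemetry and trawl surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfr)
```

## The model

A functional response links a predator's consumption to prey density. For
a predator facing several prey species at once, the multi-species
functional response (MSFR) in diet-composition form states that the share
of species $i$ in the diet is

$$\frac{c_i}{\sum_j c_j} \;=\; \frac{a_i B_i^m}{\sum_j a_j B_j^m},$$

where $B_i$ is a relative availability index for species $i$, $a_i$ is an
attack-rate (preference) coefficient, and $m$ is the shape parameter:
$m = 1$ gives the hyperbolic type II response with constant preference,
while $m > 1$ gives a sigmoidal type III response in which relatively
scarce prey are consumed disproportionately less — prey switching. Two
facts make this form practical for wild predators:

* **Catchability cancels.** If survey indices are proportional to true
  abundance, the proportionality constants fold into the $a_i$, so
  uncalibrated survey indices suffice. Only *ratios* of attack rates are
  identifiable; the package fixes the reference species (sandeel in the
  shipped configuration) at $a = 1$.
* **Subsets are unbiased.** The denominator is common to all species, so
  the diet restricted to any subset of prey and renormalised obeys the
  same equation with the same parameters. Species without availability
  estimates (e.g. gobies, essentially absent from trawl gear) can simply
  be left out. This identity is verified to $10^{-12}$ in the test suite.

Handling times cancel in the proportion form, and attack rate cannot be
separated from catchability; neither is represented.

## The pipeline

Fitting the MSFR for a stranding-sampled predator takes four stages, each
an exported function family:

1. **Diet composition** (`reconstruct_prey_mass()`, `select_main_prey()`,
   `bootstrap_diet()`). Otolith lengths from stomachs are corrected for
   digestion wear with grade-specific factors and converted to prey mass
   with species power laws. Only carcasses with decomposition codes 1-3
   are used. Species contributing at least 5% of pooled prey mass (an
   inclusive threshold, applied to the all-individuals pooled
   composition) are kept; the rest are merged into `"other"`. Sampling
   error is estimated by a nonparametric bootstrap with the individual as
   sampling unit, stratified by season (November-April versus
   May-October, matching the two survey quarters). A single-replicate
   bootstrap returns SD 0 with a warning so the operation is total.
2. **Foraging range** (`regularize_track()`, `build_mec_windows()`,
   `fit_range_glm()`, `predict_buffer()`). Telemetry tracks are clipped
   to the study region, linearly interpolated to 6-hour steps (gaps
   longer than 24 h split a track), and sliced into non-overlapping
   windows of 2, 4, 6 or 8 days. The minimum enclosing circle (MEC) of
   each window summarises movement extent; its diameter is modelled by a
   gamma GLM with log link in timeframe, age class, sex and calendar
   quarter, with two-way interactions searched by stepwise AIC and
   collinearity screened by VIF (threshold 4; flagged, not dropped, by
   default). The predicted diameter for a stranded individual's
   covariates becomes the **radius** of a circular buffer centred on the
   stranding site — deliberately twice the at-sea circle, compensating
   for the centre sitting on the coast.
3. **Prey availability** (`compute_bpue()`, `fit_prey_field()`,
   `integrate_buffer()`, `rescale_availability()`). Trawl
   catch-at-length below 400 mm (the predator's consumable size range)
   is converted to biomass per unit effort via
   $\mathrm{BPUE} = \sum_L a\,((L + 0.5e)/10)^b\,\mathrm{CPUE}_L$, then
   $\log(\mathrm{BPUE} + \delta)$ is smoothed with a depth spline plus a
   lon-lat-year tensor product (REML smoothness selection). Availability
   per stranding is the back-transformed prediction summed over sea
   cells inside the buffer; its SD comes from parametric resampling of
   the smoother coefficients. Sandeel, poorly sampled by trawls, uses an
   annual spawning-stock-biomass series instead. Finally all indices are
   rescaled so the maximum is 100.
4. **MSFR fitting** (`fit_msfr()`, `compute_dic()`,
   `response_curves()`). Observed per-individual diet proportions are
   modelled as Dirichlet around the MSFR prediction with estimated
   concentration $\tau$. Attack rates get uniform$(0, 10)$ priors (the
   reference fixed at 1); posterior mass near the upper bound is flagged.
   Sampling is adaptive random-walk Metropolis on $\log a$ (one joint
   block proposal) and $\log\tau$, two chains, with split-chain
   Gelman-Rubin diagnostics. At *every* iteration the availabilities are
   redrawn from left-truncated normals around their estimated means and
   SDs — a plug-in (cut) propagation of availability uncertainty, not
   joint inference, matching how the uncertainty was generated upstream.
   Models with $m = 1$ and $m = 1.5$ (and different buffer timeframes)
   are compared by DIC, $\mathrm{DIC} = \bar D + p_D$ with
   $p_D = \bar D - D(\bar\theta)$, availability fixed at its means for
   $D(\bar\theta)$; ties within 2 units prefer the smaller $p_D$.

`run_pipeline()` chains all four stages for every (timeframe, shape)
combination from a validated `msfr_config()`, with explicit per-stage
seeds so a rerun reproduces every number bit for bit.

## Key parameters

| Parameter | Default | Why |
|---|---|---|
| main-prey threshold | 0.05 of pooled mass, inclusive | standard main-prey rule; boundary species retained |
| interpolation step | 6 h | several positions per day without manufacturing precision |
| window stride | non-overlapping | limits pseudo-replication among windows |
| VIF threshold | 4 | conventional screen; flags, never silently drops |
| $\delta$ (log offset) | 1 g | guards zero catches; negligible at typical BPUE |
| availability rescale | global max = 100 | preserves cross-species ratios, which the MSFR depends on; `per_species` available |
| attack-rate prior | uniform$(0, 10)$ | weakly informative given the reference at 1; bound-mass flagged |
| $\tau$ prior | log-uniform$(1, 10^3)$ | scale-free over plausible compositional dispersion |
| $\epsilon$ floor | $10^{-6}$ | Dirichlet support requires strictly positive components |
| chains / draws | 2 × 10,000 after 1,000 burn-in | defaults for production; tests use scaled-down chains |

## The synthetic generator

Every input table can be generated from a `ground_truth()` object so the
whole pipeline has a recoverable target. Prey surfaces are sums of
Gaussian bumps on a projected 5-25 km grid with a wavy eastern coastline
and a depth gradient; haul CPUE is log-normal around
$\log(1 + S\,w_L)$ so a flat surface yields median catch 1 and large
amplitudes scale mean catch proportionally. Tracks are correlated random
walks confined to the sea mask, with step scale depending on age and sex
through the same coefficients that drive the range GLM. Strandings sit on
the coastline; their stomachs are filled by drawing a Poisson number of
prey items multinomially with probabilities tuned so expected *mass*
shares equal the true MSFR proportions, then inverting the otolith-mass
allometry to emit otolith records (exactly invertible when size noise is
off). Decomposition codes span 1-5 so the freshness filter is exercised.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: carcass drift, telemetry location
error, gear catchability and vessel effects, schooling/patchiness beyond
smooth bumps, digestion-rate variation beyond fixed grade factors, and
individual heterogeneity in preference. The generator's role is to
verify that each estimator recovers what it claims to estimate under its
own assumptions.

## Numerical choices and degenerate inputs

* The MEC uses the incremental support-point algorithm; collinear
  triples fall back to the widest diameter pair, and a single point
  yields radius 0. Tests compare against brute-force enumeration of all
  2-/3-point support circles.
* Geometry is done in km on an azimuthal equidistant projection centred
  on the data; distances from the centre are exact and local distortion
  is negligible at the study scale.
* Cell-in-circle membership is by cell centre — deterministic and
  consistent with the grid resolution.
* Predictions on the $\log(\mathrm{BPUE}+\delta)$ scale are
  back-transformed as $e^\eta$, a strictly positive relative index (the
  $-\delta$ correction is dropped so positivity is unconditional; the
  MSFR uses only ratios, where the 1 g offset is immaterial).
* Boundary-aware smoothing is handled by masking land cells out of
  prediction rather than a boundary-constrained (soap-film) basis; the
  MSFR consumes only buffer-integrated indices, which are insensitive to
  the difference except very near complex coastlines.
* With fewer than three distinct survey years the year margin of the
  tensor product drops to a linear year term.
* All-zero availabilities, empty season strata, unseen factor levels and
  empty point sets abort with informative errors rather than propagating
  NaNs.

## Open design decisions

The observation likelihood is the main genuinely open choice: nothing in
the diet-composition data dictates Dirichlet. It is the minimal
compositional family, its concentration absorbs overdispersion, and it
makes per-individual fitting natural; a multinomial-on-items alternative
would need item counts that grade correction partly destroys. Likewise,
whether the max-100 rescaling is global or per species changes only the
interpretation of attack-rate ratios, not fit quality; global is the
default because it preserves cross-species availability ratios, with
`per_species` as a flag. Alternative-prey levels in `response_curves()`
are each species' own observed minimum/mean/maximum. The shape parameter
is fixed per run (1 or 1.5) and chosen by DIC rather than estimated
continuously — two interpretable hypotheses rather than a poorly
identified exponent.

## Problem sizes used in validation

The shipped tests run the full pipeline on a 20 km grid with 500 hauls, 8
tracked animals and 120 strandings, and validate the sampler with 100
recovery replicates of 400 individuals at 2 chains × 2,000 iterations
and 50 model-selection replicates at 2 × 800 — sizes chosen so the suite gives stable
verdicts on estimator behaviour while remaining quick to run. The same
generative conditions at the production MCMC settings simply sharpen the
posteriors.

## Known limitations

Attack rates are preferences *relative to rescaled indices*: they are not
comparable across datasets with different rescaling, and not separable
from catchability. Stranded animals are not a random sample of the
population (juveniles over-represented), so the fitted response describes
the sampled population. The plug-in availability draws understate joint
uncertainty relative to full latent-variable inference. Scenario
predictions assume unchanged spatial patterns, stranding locations and
energy densities; they rescale availability by stock-level ratios only.

One consequence of the cut (plug-in) treatment of availability deserves
emphasis: *estimation error in availability attenuates the switching
signal*. When the response is evaluated at estimated rather than true
availabilities, errors-in-variables flatten the apparent curvature, and
DIC can prefer the hyperbolic ($m = 1$) shape even when the generative
response is sigmoidal — we observe exactly this in end-to-end synthetic
runs, while shape selection on data with known availabilities is
reliable. Timeframe selection, by contrast, is robust end to end.
Conclusions about $m$ drawn from noisy availability fields should
therefore be read as conservative with respect to switching.
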