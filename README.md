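# msfr

Multi-species functional responses for marine predators, estimated by
integrating three data streams that never observe the same animal at the
same time: **diet** from stomach contents of stranded carcasses,
**foraging range** from satellite telemetry, and **prey availability**
from bottom-trawl surveys.

## The problem

How does a predator's diet respond when the mix of available prey
changes? For a small cetacean like the harbour porpoise this cannot be
observed directly: consumption is only measurable post mortem, the
animal's recent whereabouts are unknown, and prey abundance is sampled
by surveys on a coarse grid. `msfr` implements a pipeline that joins
these pieces and fits the multi-species functional response (MSFR) in
diet-composition form,

```
c_i / Σ_j c_j  =  a_i B_i^m / Σ_j a_j B_j^m
```

where `B_i` is a relative availability index for prey species `i`, `a_i`
an attack-rate (preference) coefficient with the reference species fixed
at 1, and `m` the shape: `m = 1` is a hyperbolic type II response,
`m > 1` a sigmoidal type III response implying prey switching. Because
only ratios enter, uncalibrated survey indices suffice (catchability
folds into `a_i`), and any subset of prey can be modelled without bias.

The pipeline stages are:

1. **Diet** — otolith lengths corrected for digestion wear, converted to
   prey mass by allometry; ≥ 5% species kept as main prey; sampling error
   by a season-stratified bootstrap over individuals
   (`reconstruct_prey_mass()`, `bootstrap_diet()`).
2. **Foraging range** — telemetry tracks regularised and sliced into 2-8
   day windows; minimum-enclosing-circle diameters modelled by a gamma
   GLM (log link, AIC selection, VIF screening); the predicted diameter
   becomes the radius of a buffer centred on each stranding
   (`fit_range_glm()`, `predict_buffer()`).
3. **Availability** — trawl catch-at-length (< 400 mm) converted to
   biomass per unit effort, smoothed over depth, space and year
   (`mgcv`, REML), integrated over each buffer with coefficient-resampling
   SDs; a spawning-stock-biomass series stands in for trawl-shy sandeel;
   indices rescaled to max 100 (`fit_prey_field()`,
   `integrate_buffer()`).
4. **MSFR fit** — Dirichlet observation model, adaptive random-walk
   Metropolis on log attack rates, availability uncertainty propagated
   by per-iteration truncated-normal redraws, type II vs III compared by
   DIC (`fit_msfr()`, `compute_dic()`, `response_curves()`).

A synthetic-data module (`ground_truth()`, `sim_prey_surveys()`,
`sim_tracks()`, `sim_strandings()`, `sim_diet_observations()`) generates
all four input tables from known parameters, so every stage — and the
pipeline end to end (`run_pipeline()`) — is validated by parameter
recovery.

## Worked example

Attack-rate recovery on synthetic diet data (400 individuals, true rates
1, 0.5, 0.25, 0.1, sigmoidal response `m = 1.5`):

```r
library(msfr)
a_true <- c(sandeel = 1, whiting = 0.5, herring = 0.25, cod = 0.1)
obs <- sim_diet_observations(400, a_true, shape_m = 1.5, tau = 50, seed = 42)
fit <- fit_msfr(obs, m = 1.5, iter = 2000, burn = 500, seed = 1)
tidy(fit)
#> # A tibble: 4 × 6
#>   term      estimate std.error conf.low conf.high  rhat
#>   <chr>        <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 a_cod        0.103   0.00297   0.0971     0.109  1.01
#> 2 a_herring    0.252   0.00638   0.239      0.264  1.01
#> 3 a_whiting    0.491   0.0101    0.471      0.511  1.01
#> 4 tau         45.7     1.81     42.2       49.5    1.00
```

Every generative attack rate sits inside its 95% credible interval; `tau`
is the estimated Dirichlet concentration of diet observations around the
response.

Scenario arithmetic on the shipped southern North Sea table (diet in a
high-sandeel reference year versus a low-sandeel target year, with prey
energy densities in kJ/g):

```r
sc <- north_sea_scenario()
en <- sc[c("species", "energy_kj_g")]
m_ref <- data.frame(species = sc$species, pct_mass = sc$pct_mass_2011)
m_tgt <- data.frame(species = sc$species, pct_mass = sc$pct_mass_2020)

mass_to_energy_shares(m_ref, en)
#>   species pct_mass pct_energy
#> 1     cod      5.9   5.009603
#> 2 herring      4.1   5.138987
#> 3 sandeel     26.6  31.189730
#> 4   sprat      3.8   5.838472
#> 5 whiting      9.5   8.258365
#> 6   other     50.1  44.564844

consumption_deltas(m_ref, m_tgt, en)
#> # A tibble: 1 × 5
#>   ed_ref_kj_g ed_target_kj_g delta_grams_per_day delta_kj_per_day pct_change
#>         <dbl>          <dbl>               <dbl>            <dbl>      <dbl>
#> 1        4.95           4.85                26.8            -163.       1.97
```

Read: sandeel carries 31.2% of dietary energy on only 26.6% of mass in
the reference year; after the shift to the low-sandeel diet, a porpoise
holding its 6.7 MJ/day energy budget must eat ~27 g/day more, or at a
fixed 1.7 kg/day it loses ~163 kJ/day — about a 2% change either way.

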