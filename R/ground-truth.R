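#' Generative ground truth for the synthetic pipeline
#'
#' Bundles every parameter the synthetic-data generators need: the true
#' multi-species functional response (attack rates, with the sandeel rate
#' fixed at 1, and shape `m`), Gaussian-bump prey surfaces per species and
#' survey quarter, the gamma-GLM coefficients that drive foraging-range
#' diameters, length-weight and otolith-mass allometries, wear-grade
#' correction factors, energy densities, and a sandeel spawning-stock
#' biomass (SSB) series. Downstream recovery tests compare estimates
#' against this object.
#'
#' Defaults are chosen to be realistic for a small-cetacean shelf-sea
#' system: five prey species with attack rates spanning an order of
#' magnitude, a sigmoidal response (`m = 1.5`), 2-day foraging ranges of
#' roughly 30 km growing to ~100 km at 8 days, ~1 kg of prey per stomach,
#' and energy densities of 4-8 kJ/g.
#'
#' @param species Character vector of prey species; the first is the
#'   reference species whose attack rate is fixed at 1 (default sandeel).
#' @param attack_rates Named positive vector, one per species; reference
#'   species must be 1.
#' @param shape_m Functional-response shape: 1 (hyperbolic, type II) or
#'   1.5 (sigmoidal, type III).
#' @param range_coefs Named coefficients of the log-link gamma GLM for MEC
#'   diameter (km); see [sim_range_windows()] for the design.
#' @param range_dispersion Gamma dispersion (squared CV) of MEC diameters.
#' @param ssb Tibble `year`, `ssb` for the reference species.
#' @param stomach_mean_kg,stomach_cv Log-normal total stomach content mass.
#' @param mean_items Mean number of prey items per stomach (Poisson).
#' @param length_sd Log-scale SD of individual fish size around the species
#'   typical size; 0 makes otolith emission exactly invertible.
#' @param grades Tibble `grade`, `factor`: wear-grade correction factors
#'   (observed otolith length times factor = undigested length).
#' @param decomp_probs Probabilities of carcass decomposition codes 1-5.
#' @param availability_scale `"global"` or `"per_species"`: how the
#'   generator rescales true availabilities to a max of 100 before
#'   evaluating the functional response.
#' @return An object of class `msfr_ground_truth` (a list).
#' @export
#' @examples
#' gt <- ground_truth()
#' gt$species_pars
ground_truth <- function(
    species = c("sandeel", "whiting", "herring", "sprat", "cod"),
    attack_rates = c(sandeel = 1, whiting = 0.12, herring = 0.101,
                     sprat = 0.238, cod = 0.058),
    shape_m = 1.5,
    range_coefs = default_range_coefs(),
    range_dispersion = 0.16,
    ssb = tibble(year = 2006:2015,
                 ssb = c(180, 220, 150, 130, 260, 310, 170, 140, 200, 120)),
    stomach_mean_kg = 1.0, stomach_cv = 0.5,
    mean_items = 40, length_sd = 0.15,
    grades = tibble(grade = 1:3, factor = c(1.0, 1.1, 1.25)),
    decomp_probs = c(0.25, 0.25, 0.2, 0.2, 0.1),
    availability_scale = c("global", "per_species")) {
  availability_scale <- match.arg(availability_scale)
  attack_rates <- attack_rates[species]
  if (anyNA(attack_rates) || any(attack_rates <= 0)) {
    abort("`attack_rates` must be positive and named for every species")
  }
  if (abs(attack_rates[[1]] - 1) > 1e-12) {
    abort(sprintf("reference species '%s' must have attack rate 1", species[1]))
  }
  if (shape_m < 1) abort("`shape_m` must be >= 1")
  if (length(decomp_probs) != 5 || any(decomp_probs < 0)) {
    abort("`decomp_probs` must be 5 non-negative weights for codes 1-5")
  }

  pars <- tibble(
    species = species,
    attack_rate = unname(attack_rates),
    # Eq.-1-style survey length-weight conversion (length in mm, mass in g)
    lw_a = c(0.004, 0.006, 0.006, 0.008, 0.007)[seq_along(species)],
    lw_b = c(3.1, 3.0, 3.05, 2.95, 3.05)[seq_along(species)],
    lw_e = c(10, 10, 10, 5, 10)[seq_along(species)],
    typical_length_mm = c(120, 200, 180, 100, 250)[seq_along(species)],
    # otolith length (mm) -> fish mass (g) power law
    oto_a = c(1.6, 1.2, 1.4, 1.1, 1.3)[seq_along(species)],
    oto_b = c(2.6, 2.8, 2.7, 2.9, 2.75)[seq_along(species)],
    energy_kj_g = c(5.8, 4.3, 6.2, 7.6, 4.2)[seq_along(species)]
  )

  structure(
    list(
      species_pars = pars,
      shape_m = shape_m,
      bumps = default_prey_bumps(species),
      range_coefs = range_coefs,
      range_dispersion = range_dispersion,
      ssb = ssb,
      stomach_mean_kg = stomach_mean_kg,
      stomach_cv = stomach_cv,
      mean_items = mean_items,
      length_sd = length_sd,
      grades = grades,
      decomp_probs = decomp_probs / sum(decomp_probs),
      availability_scale = availability_scale
    ),
    class = "msfr_ground_truth"
  )
}

#' Default gamma-GLM coefficients for foraging-range diameter
#'
#' Log-link coefficients giving 2-day MEC diameters near 30 km rising to
#' ~100 km for 8-day windows, slightly smaller ranges for juveniles and
#' males, and a spring (Q2) enlargement. Baseline: 2-day window, adult
#' female, calendar quarter Q1.
#'
#' @return A named numeric vector.
#' @export
default_range_coefs <- function() {
  c("(Intercept)" = log(33),
    "timeframe4" = log(56 / 33), "timeframe6" = log(80 / 33),
    "timeframe8" = log(104 / 33),
    "age_classjuvenile" = -0.13, "sexM" = -0.07,
    "quarterQ2" = 0.21, "quarterQ3" = -0.05, "quarterQ4" = -0.04)
}

# Gaussian-bump prey surfaces: per species and survey quarter, a couple of
# hotspots on the projected-km grid whose amplitude drifts across years.
default_prey_bumps <- function(species) {
  ns <- length(species)
  base <- tibble(
    species = rep(species, each = 2),
    bump = rep(1:2, ns),
    cx = rep(c(-60, 20), ns) + seq(-30, 30, length.out = 2 * ns),
    cy = rep(c(-40, 60), ns) + seq(25, -25, length.out = 2 * ns),
    sd_km = rep(c(55, 70), ns),
    amp = rep(c(30, 18), ns),
    year_slope = rep(c(0.03, -0.02), ns)
  )
  crossing(base, quarter = c("Q1", "Q3")) |>
    mutate(amp = .data$amp * ifelse(.data$quarter == "Q3", 1.25, 1))
}

#' Evaluate the true prey surface
#'
#' Sum of the ground truth's Gaussian bumps for one species, quarter and
#' year at projected coordinates `(x, y)`; the relative-density scale the
#' synthetic survey CPUE is drawn around.
#'
#' @param gt A [ground_truth()] object.
#' @param species,quarter,year Scalars identifying the surface.
#' @param x,y Numeric vectors of projected km coordinates.
#' @return Numeric vector of non-negative surface values.
#' @export
true_surface <- function(gt, species, quarter, year, x, y) {
  b <- gt$bumps[gt$bumps$species == species & gt$bumps$quarter == quarter, ]
  year0 <- min(gt$ssb$year)
  val <- rep(0, length(x))
  for (i in seq_len(nrow(b))) {
    amp <- max(0, b$amp[i] * (1 + b$year_slope[i] * (year - year0)))
    val <- val + amp *
      exp(-((x - b$cx[i])^2 + (y - b$cy[i])^2) / (2 * b$sd_km[i]^2))
  }
  val
}
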