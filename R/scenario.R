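# Scenario prediction: diet under rescaled prey availability, and the
# biomass/energy arithmetic that converts diet shares between mass and
# energy terms and into daily-consumption changes.

#' Example scenario table: southern North Sea harbour porpoise
#'
#' Predicted diet composition (% of total prey mass) of an average adult
#' male harbour porpoise in the southern North Sea for a high-sandeel
#' reference year (2011) and a low-sandeel target year (2020, availability
#' rescaled by stock-assessment SSB ratios), together with prey energy
#' densities (kJ/g; the goby value stands in for the mixed "other"
#' category). Ships as a plain-text file under `inst/extdata/` and is the
#' worked example for the energy-share and consumption arithmetic.
#'
#' @return A tibble `species`, `pct_mass_2011`, `pct_mass_2020`,
#'   `energy_kj_g`.
#' @export
#' @examples
#' north_sea_scenario()
north_sea_scenario <- function() {
  as_tibble(read.csv(system.file("extdata", "north_sea_scenario.csv",
                                 package = "msfr"),
                     stringsAsFactors = FALSE))
}

#' Predict diet composition under rescaled availability
#'
#' Multiplies each species' availability by its SSB ratio (target year /
#' reference year), evaluates the functional response at every posterior
#' draw, and returns posterior mean shares as percentages (with credible
#' intervals).
#'
#' @param fit An [fit_msfr()] object.
#' @param ssb_scalers Named vector of availability ratios, one per
#'   species (1 = unchanged).
#' @param conf_level Credible-interval level.
#' @return A tibble `species`, `pct_mass`, `lower`, `upper`.
#' @export
predict_scenario_diet <- function(fit, ssb_scalers = NULL,
                                  conf_level = 0.95) {
  if (is.null(ssb_scalers)) {
    ssb_scalers <- setNames(rep(1, length(fit$species)), fit$species)
  }
  missing <- setdiff(fit$species, names(ssb_scalers))
  if (length(missing)) {
    abort(paste0("missing SSB scaler for: ", paste(missing, collapse = ", ")))
  }
  if (any(ssb_scalers < 0)) abort("SSB scalers must be non-negative")
  B <- sweep(fit$avail_mean, 2, ssb_scalers[colnames(fit$avail_mean)], "*")
  d <- pooled_draws(fit)
  pr <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  # per-draw population mean diet share, averaged over individuals
  shares <- apply(d$a, 1, function(a) {
    colMeans(msfr_proportions(setNames(a, fit$species), B, fit$m))
  })
  tibble(
    species = fit$species,
    pct_mass = 100 * unname(rowMeans(shares)),
    lower = 100 * unname(apply(shares, 1, quantile, pr[1])),
    upper = 100 * unname(apply(shares, 1, quantile, pr[2]))
  )
}

#' Convert diet mass shares to energy shares
#'
#' `%E_i = %M_i E_i / sum_j %M_j E_j * 100`, with `E_i` the species
#' energy density (kJ/g). Rounded published inputs are tolerated: the
#' mass shares must sum to 100 within 0.5.
#'
#' @param mass_shares Tibble with `species` and `pct_mass`.
#' @param energy Tibble with `species` and `energy_kj_g`.
#' @return A tibble `species`, `pct_mass`, `pct_energy`.
#' @export
#' @examples
#' mass_to_energy_shares(
#'   tibble::tibble(species = c("a", "b"), pct_mass = c(50, 50)),
#'   tibble::tibble(species = c("a", "b"), energy_kj_g = c(6, 2))
#' )
mass_to_energy_shares <- function(mass_shares, energy) {
  if (abs(sum(mass_shares$pct_mass) - 100) > 0.5) {
    abort("mass shares must sum to 100 (within 0.5)")
  }
  missing <- setdiff(mass_shares$species, energy$species)
  if (length(missing)) {
    abort(paste0("missing energy density for: ",
                 paste(missing, collapse = ", ")))
  }
  mass_shares |>
    left_join(energy[c("species", "energy_kj_g")], by = "species") |>
    mutate(pct_energy = 100 * .data$pct_mass * .data$energy_kj_g /
             sum(.data$pct_mass * .data$energy_kj_g)) |>
    select("species", "pct_mass", "pct_energy")
}

#' Daily-consumption changes between two diet compositions
#'
#' From the mean diet energy density `e = sum_i %M_i E_i / 100` (kJ/g) of
#' the reference and target compositions: the extra biomass needed per day
#' to hold energy intake constant, the energy shortfall per day at
#' constant biomass intake, and the relative change.
#'
#' @param ref,target Tibbles with `species`, `pct_mass`.
#' @param energy Tibble with `species`, `energy_kj_g`.
#' @param daily_mass_kg Daily biomass intake held fixed for the energy
#'   delta (default 1.7 kg, an average adult male porpoise).
#' @param daily_energy_mj Daily energy requirement held fixed for the
#'   biomass delta (default 6.7 MJ).
#' @return A one-row tibble: `ed_ref_kj_g`, `ed_target_kj_g`,
#'   `delta_grams_per_day`, `delta_kj_per_day`, `pct_change`.
#' @export
consumption_deltas <- function(ref, target, energy,
                               daily_mass_kg = 1.7, daily_energy_mj = 6.7) {
  ed <- function(comp) {
    comp <- left_join(comp, energy[c("species", "energy_kj_g")],
                      by = "species")
    if (anyNA(comp$energy_kj_g)) abort("missing energy density")
    sum(comp$pct_mass * comp$energy_kj_g) / 100
  }
  ed_ref <- ed(ref); ed_target <- ed(target)
  grams_ref <- daily_energy_mj * 1000 / ed_ref
  grams_target <- daily_energy_mj * 1000 / ed_target
  tibble(
    ed_ref_kj_g = ed_ref, ed_target_kj_g = ed_target,
    delta_grams_per_day = grams_target - grams_ref,
    delta_kj_per_day = daily_mass_kg * 1000 * (ed_target - ed_ref),
    pct_change = 100 * (grams_target - grams_ref) / grams_ref
  )
}

#' Per-species relative change between two compositions
#'
#' `100 (target - ref) / ref` per species; species absent from the
#' reference diet get `NA` (undefined relative change).
#'
#' @param ref,target Tibbles with `species`, `pct_mass`.
#' @return A tibble `species`, `ref`, `target`, `pct_change`.
#' @export
#' @examples
#' relative_change(tibble::tibble(species = "sandeel", pct_mass = 26.6),
#'                 tibble::tibble(species = "sandeel", pct_mass = 9.8))
relative_change <- function(ref, target) {
  out <- full_join_shares(ref, target)
  mutate(out, pct_change = ifelse(.data$ref == 0, NA_real_,
                                  100 * (.data$target - .data$ref) / .data$ref))
}

full_join_shares <- function(ref, target) {
  dplyr::full_join(
    rename(ref[c("species", "pct_mass")], ref = "pct_mass"),
    rename(target[c("species", "pct_mass")], target = "pct_mass"),
    by = "species"
  )
}
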