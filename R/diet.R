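# Diet composition from stomach contents: otolith-based prey-mass
# reconstruction, main-prey selection, carcass filtering and a stratified
# individual-level bootstrap.

#' Reconstruct prey masses from otolith records
#'
#' Observed otolith lengths are corrected for digestion wear with
#' grade-specific factors (undigested length = observed length x factor)
#' and converted to fish mass with a species-specific power law
#' `mass = a * length^b`, times the record's otolith count. Correction
#' factors and allometries are configuration tables; example tables
#' matching the synthetic generator ship with the package.
#'
#' @param otoliths Tibble with `species`, `otolith_length_mm`,
#'   `wear_grade`, `count` (and typically `stranding_id`).
#' @param grade_corrections Tibble `grade`, `factor`.
#' @param oto_allometry Tibble `species`, `oto_a`, `oto_b`.
#' @return The input tibble with columns `corrected_length_mm` and
#'   `mass_g` appended.
#' @export
#' @examples
#' reconstruct_prey_mass(
#'   tibble::tibble(species = "whiting", otolith_length_mm = 10,
#'                  wear_grade = 1, count = 1),
#'   grade_corrections = tibble::tibble(grade = 1, factor = 1),
#'   oto_allometry = tibble::tibble(species = "whiting", oto_a = 2, oto_b = 1)
#' )
reconstruct_prey_mass <- function(otoliths, grade_corrections, oto_allometry) {
  stopifnot(all(c("species", "otolith_length_mm", "wear_grade", "count")
                %in% names(otoliths)))
  bad_sp <- setdiff(unique(otoliths$species), oto_allometry$species)
  if (length(bad_sp)) {
    abort(paste0("no otolith-mass allometry for species: ",
                 paste(bad_sp, collapse = ", ")))
  }
  bad_gr <- setdiff(unique(otoliths$wear_grade), grade_corrections$grade)
  if (length(bad_gr)) {
    abort(paste0("no correction factor for wear grade(s): ",
                 paste(bad_gr, collapse = ", ")))
  }
  if (any(otoliths$otolith_length_mm <= 0)) {
    abort("otolith lengths must be positive")
  }
  otoliths |>
    left_join(grade_corrections, by = c(wear_grade = "grade")) |>
    left_join(oto_allometry, by = "species") |>
    mutate(
      corrected_length_mm = .data$otolith_length_mm * .data$factor,
      mass_g = .data$count * .data$oto_a * .data$corrected_length_mm^.data$oto_b
    ) |>
    select(-"factor", -"oto_a", -"oto_b")
}

#' Keep only fresh carcasses
#'
#' Retains strandings with decomposition code below `max_code + 1`
#' (default: codes 1-3), balancing carcass freshness against sample size,
#' and reports how many records were dropped.
#'
#' @param strandings Tibble with a `decomposition_code` column.
#' @param max_code Largest code retained.
#' @return The filtered tibble.
#' @export
filter_carcasses <- function(strandings, max_code = 3) {
  keep <- strandings$decomposition_code <= max_code
  dropped <- sum(!keep)
  inform(sprintf("filter_carcasses: retained %d of %d strandings (%d dropped)",
                 sum(keep), length(keep), dropped))
  out <- strandings[keep, , drop = FALSE]
  if (nrow(out) == 0) warn("no strandings left after decomposition filter")
  out
}

#' Pooled diet composition over a set of individuals
#'
#' @param masses Tibble with `species` and `mass_g` (e.g. the output of
#'   [reconstruct_prey_mass()], already restricted to retained
#'   individuals).
#' @return A tibble `species`, `mass_g`, `prop` sorted by decreasing share.
#' @export
pooled_composition <- function(masses) {
  masses |>
    group_by(.data$species) |>
    summarise(mass_g = sum(.data$mass_g), .groups = "drop") |>
    mutate(prop = .data$mass_g / sum(.data$mass_g)) |>
    arrange(dplyr::desc(.data$prop))
}

#' Select main prey species from the pooled composition
#'
#' Species contributing at least `threshold` (default 5%) of the pooled
#' prey mass are kept individually; the rest are merged into `"other"`.
#' Species listed in `force_other` (e.g. gobies, for which no availability
#' can be estimated) are merged regardless of their share.
#'
#' @param composition Output of [pooled_composition()].
#' @param threshold Minimum pooled mass share (boundary inclusive).
#' @param force_other Species always sent to `"other"`.
#' @return Character vector of main prey species.
#' @export
#' @examples
#' comp <- tibble::tibble(species = c("a", "b", "c"),
#'                        mass_g = c(50, 45, 5), prop = c(.5, .45, .05))
#' select_main_prey(comp)
select_main_prey <- function(composition, threshold = 0.05,
                             force_other = character(0)) {
  main <- composition$species[composition$prop >= threshold]
  setdiff(main, force_other)
}

#' Merge non-main species into an "other" category
#'
#' Preserves total mass exactly: everything not in `main` is relabelled
#' `"other"`.
#'
#' @param masses Tibble with `species` and `mass_g`.
#' @param main Character vector of species kept individually.
#' @return `masses` with `species` relabelled.
#' @export
lump_other <- function(masses, main) {
  mutate(masses, species = ifelse(.data$species %in% main,
                                  .data$species, "other"))
}

#' Bootstrap diet composition, stratified by season
#'
#' Nonparametric bootstrap with stranded individuals as the sampling unit:
#' individuals are resampled with replacement within season strata (Q1 =
#' November-April, Q3 = May-October), pooled mass proportions are computed
#' per replicate, and the mean and SD per species summarise sampling error.
#'
#' @param strandings Tibble with `stranding_id` and `date` (or a
#'   `season_quarter` column) for the retained individuals.
#' @param masses Tibble with `stranding_id`, `species`, `mass_g` (species
#'   already lumped as desired).
#' @param n_boot Number of bootstrap replicates (>= 1; a single replicate
#'   returns SD 0 with a warning).
#' @param seed Optional integer seed.
#' @return An object of class `diet_composition`: a tibble `species`,
#'   `mean`, `sd` (proportions of total prey mass), with attributes
#'   `n_individuals`, `n_boot` and `stratification`.
#' @export
bootstrap_diet <- function(strandings, masses, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(strandings) == 0) abort("no strandings to bootstrap")
  if (n_boot == 1) warn("single bootstrap replicate: SD reported as 0")
  strandings <- as_tibble(strandings)
  if (!"season_quarter" %in% names(strandings)) {
    strandings$season_quarter <- assign_season(strandings$date)
  }
  strata <- split(strandings$stranding_id, strandings$season_quarter)
  empty <- names(strata)[lengths(strata) == 0]
  if (length(empty)) {
    abort(paste0("empty season stratum: ", paste(empty, collapse = ", ")))
  }

  species <- sort(unique(masses$species))
  # individual x species mass matrix for fast replicate pooling
  M <- masses |>
    group_by(.data$stranding_id, .data$species) |>
    summarise(mass_g = sum(.data$mass_g), .groups = "drop") |>
    pivot_wider(names_from = "species", values_from = "mass_g",
                values_fill = 0)
  ids <- M$stranding_id
  M <- as.matrix(M[, species, drop = FALSE])
  rownames(M) <- ids

  reps <- matrix(0, n_boot, length(species),
                 dimnames = list(NULL, species))
  for (b in seq_len(n_boot)) {
    draw <- unlist(lapply(strata, function(s) {
      s[sample.int(length(s), length(s), replace = TRUE)]
    }), use.names = FALSE)
    tot <- colSums(M[match(draw, ids), , drop = FALSE], na.rm = TRUE)
    reps[b, ] <- tot / sum(tot)
  }

  out <- tibble(
    species = species,
    mean = unname(colMeans(reps)),
    sd = if (n_boot == 1) rep(0, length(species))
         else unname(apply(reps, 2, sd))
  )
  structure(out, class = c("diet_composition", class(out)),
            n_individuals = nrow(strandings), n_boot = n_boot,
            stratification = "season_quarter")
}
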