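# End-to-end orchestration: configuration, validation, and the four-stage
# pipeline (diet -> foraging range -> availability -> MSFR fitting), run
# for every requested (timeframe, shape) combination.

#' Pipeline configuration
#'
#' Collects every setting the pipeline needs, with reproducible seeds for
#' each stochastic stage. Either a `synthetic` block (tables generated
#' from a [ground_truth()]) or a `paths` block (CSV files with the
#' documented columns) must be supplied; the default runs a small
#' synthetic study.
#'
#' @param synthetic List `n_hauls`, `n_animals`, `n_strandings`,
#'   `track_days`, or NULL when reading from `paths`.
#' @param paths Named list of CSV paths (`hauls`, `tracks`, `strandings`,
#'   `otoliths`), or NULL.
#' @param gt A [ground_truth()] (generation parameters; also supplies the
#'   grade-correction, allometry and SSB tables for synthetic runs).
#' @param cell_km Grid resolution.
#' @param timeframes Subset of `c(2, 4, 6, 8)` days.
#' @param shape_m Shape parameters to compare (typically `c(1, 1.5)`).
#' @param mcmc List `chains`, `iter`, `burn`.
#' @param n_boot Diet bootstrap replicates.
#' @param n_draws Coefficient draws per buffer integral.
#' @param availability_scale `"global"` or `"per_species"` rescaling.
#' @param ref_species Reference species (attack rate fixed at 1,
#'   SSB-indexed availability).
#' @param main_prey_threshold Pooled-share threshold for main prey.
#' @param seeds Named integer list: `simulate`, `diet`, `availability`,
#'   `mcmc`.
#' @return A list of class `msfr_config`.
#' @export
msfr_config <- function(synthetic = list(n_hauls = 800, n_animals = 12,
                                         n_strandings = 150,
                                         track_days = 40),
                        paths = NULL,
                        gt = ground_truth(),
                        cell_km = 10,
                        timeframes = c(2, 4, 6, 8),
                        shape_m = c(1, 1.5),
                        mcmc = list(chains = 2, iter = 2000, burn = 500),
                        n_boot = 500,
                        n_draws = 100,
                        availability_scale = "global",
                        ref_species = "sandeel",
                        main_prey_threshold = 0.05,
                        seeds = list(simulate = 101, diet = 202,
                                     availability = 303, mcmc = 404)) {
  structure(
    list(synthetic = synthetic, paths = paths, gt = gt, cell_km = cell_km,
         timeframes = timeframes, shape_m = shape_m, mcmc = mcmc,
         n_boot = n_boot, n_draws = n_draws,
         availability_scale = availability_scale,
         ref_species = ref_species,
         main_prey_threshold = main_prey_threshold, seeds = seeds),
    class = "msfr_config"
  )
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; an empty result means the configuration
#' is runnable.
#'
#' @param config An [msfr_config()] list.
#' @return A tibble `field`, `message` (zero rows when valid).
#' @export
#' @examples
#' validate_config(msfr_config())
validate_config <- function(config) {
  issues <- list()
  add <- function(field, message) {
    issues[[length(issues) + 1]] <<- tibble(field = field, message = message)
  }
  if (is.null(config$synthetic) && is.null(config$paths)) {
    add("synthetic/paths", "either a synthetic block or input paths required")
  }
  if (!is.null(config$paths)) {
    need <- c("hauls", "tracks", "strandings", "otoliths")
    miss <- setdiff(need, names(config$paths))
    if (length(miss)) add("paths", paste("missing path(s):",
                                         paste(miss, collapse = ", ")))
  }
  bad_tf <- setdiff(config$timeframes, c(2, 4, 6, 8))
  if (length(bad_tf) || length(config$timeframes) == 0) {
    add("timeframes", paste0("timeframes must be a non-empty subset of ",
                             "{2, 4, 6, 8}; got: ",
                             paste(config$timeframes, collapse = ", ")))
  }
  if (any(config$shape_m < 1)) add("shape_m", "shape parameters must be >= 1")
  for (s in c("simulate", "diet", "availability", "mcmc")) {
    v <- config$seeds[[s]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v)) {
      add(paste0("seeds$", s), "missing or non-numeric seed")
    }
  }
  for (f in c("chains", "iter", "burn")) {
    v <- config$mcmc[[f]]
    if (is.null(v) || v < 1) add(paste0("mcmc$", f), "must be >= 1")
  }
  if (!config$availability_scale %in% c("global", "per_species")) {
    add("availability_scale", "must be 'global' or 'per_species'")
  }
  if (length(issues) == 0) {
    tibble(field = character(0), message = character(0))
  } else {
    list_rbind(issues)
  }
}

#' Run the full pipeline
#'
#' Generates (or loads) the four input tables, then runs the four stages:
#' diet composition with bootstrap, foraging-range model and buffers,
#' prey-field fitting and buffer integration, and MSFR fitting for every
#' (timeframe, shape) combination, compared by DIC. All stage seeds come
#' from the configuration, so a rerun with the same configuration gives
#' identical results.
#'
#' @param config An [msfr_config()]; validated before running.
#' @return A list of class `msfr_pipeline`: inputs, `diet`
#'   (bootstrap summary), `range_model`, `fields`, `availability`,
#'   `observations`, `fits` (named by `tf<days>_m<shape>`), `dic`
#'   (comparison table with a `timeframe` column), `main_prey`, `config`
#'   and `config_hash`.
#' @export
run_pipeline <- function(config = msfr_config()) {
  issues <- validate_config(config)
  if (nrow(issues) > 0) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", issues$field, ": ", issues$message,
                        collapse = "\n")))
  }
  gt <- config$gt
  grid <- study_grid(cell_km = config$cell_km)
  sp <- gt$species_pars

  # stage 0: inputs
  if (!is.null(config$synthetic)) {
    set.seed(config$seeds$simulate)
    hauls <- sim_prey_surveys(gt, grid, n_hauls = config$synthetic$n_hauls)
    tracks <- sim_tracks(gt, grid, n_animals = config$synthetic$n_animals,
                         days = config$synthetic$track_days)
    st <- sim_strandings(gt, grid,
                         n_strandings = config$synthetic$n_strandings)
    strandings <- st$strandings; otoliths <- st$otoliths
  } else {
    rd <- function(p) as_tibble(read.csv(p, stringsAsFactors = FALSE))
    hauls <- rd(config$paths$hauls)
    tracks <- rd(config$paths$tracks)
    tracks$timestamp <- as.POSIXct(tracks$timestamp, tz = "UTC")
    strandings <- rd(config$paths$strandings)
    strandings$date <- as.Date(strandings$date)
    otoliths <- rd(config$paths$otoliths)
  }

  # stage 1: diet composition
  masses <- reconstruct_prey_mass(
    otoliths,
    grade_corrections = gt$grades,
    oto_allometry = sp[c("species", "oto_a", "oto_b")]
  )
  retained <- filter_carcasses(strandings)
  masses <- filter(masses, .data$stranding_id %in% retained$stranding_id)
  pooled <- pooled_composition(masses)
  main <- select_main_prey(pooled, threshold = config$main_prey_threshold)
  if (!config$ref_species %in% main) {
    abort(sprintf("reference species '%s' fell below the main-prey threshold",
                  config$ref_species))
  }
  diet <- bootstrap_diet(retained, lump_other(masses, main),
                         n_boot = config$n_boot, seed = config$seeds$diet)

  # stage 2: foraging range
  tracks <- filter_region(tracks)
  reg <- regularize_track(tracks)
  windows <- list_rbind(map(config$timeframes,
                            function(tf) build_mec_windows(reg, tf)))
  range_model <- fit_range_glm(windows)

  # stage 3: prey availability (main prey only; the response over a prey
  # subset is unbiased for the subset, so non-main species drop out)
  retained <- mutate(retained,
                     year = as.integer(format(.data$date, "%Y")),
                     season_quarter = assign_season(.data$date))
  set.seed(config$seeds$availability)
  bpue <- compute_bpue(filter(hauls, .data$species %in% main),
                       sp[c("species", "lw_a", "lw_b", "lw_e")])
  fields <- list()
  for (s in setdiff(main, config$ref_species)) {
    for (q in intersect(c("Q1", "Q3"), unique(bpue$quarter))) {
      b <- filter(bpue, .data$species == s, .data$quarter == q)
      if (nrow(b) == 0) next
      fields[[paste(s, q, sep = ".")]] <- fit_prey_field(b, grid)
    }
  }

  observations <- list(); buffers_all <- list()
  for (tf in config$timeframes) {
    buffers <- predict_buffer(range_model, retained, tf) |>
      left_join(retained[c("stranding_id", "year", "season_quarter")],
                by = "stranding_id")
    buffers_all[[as.character(tf)]] <- buffers
    avail <- estimate_availability(
      fields, buffers, ssb = gt$ssb, ref_species = config$ref_species,
      n_draws = config$n_draws, scale = config$availability_scale
    )
    props <- masses |>
      filter(.data$species %in% main) |>
      group_by(.data$stranding_id, .data$species) |>
      summarise(mass_g = sum(.data$mass_g), .groups = "drop_last") |>
      mutate(prop = .data$mass_g / sum(.data$mass_g)) |>
      ungroup() |>
      select("stranding_id", "species", "prop")
    obs <- avail |>
      inner_join(props, by = c("stranding_id", "species")) |>
      rename(avail_mean = "mean", avail_sd = "sd")
    # keep individuals with a full species record
    complete <- obs |> count(.data$stranding_id) |>
      filter(.data$n == length(main)) |> pull(.data$stranding_id)
    observations[[as.character(tf)]] <-
      filter(obs, .data$stranding_id %in% complete)
  }

  # stage 4: MSFR fits and DIC comparison
  fits <- list()
  set.seed(config$seeds$mcmc)
  for (tf in config$timeframes) {
    for (m in config$shape_m) {
      fits[[sprintf("tf%d_m%g", tf, m)]] <- fit_msfr(
        observations[[as.character(tf)]], m = m,
        ref_species = config$ref_species,
        chains = config$mcmc$chains, iter = config$mcmc$iter,
        burn = config$mcmc$burn
      )
    }
  }
  dic <- dic_table(fits) |>
    mutate(timeframe = as.integer(sub("tf(\\d+)_m.*", "\\1", .data$model)),
           .after = "model")

  structure(
    list(hauls = hauls, tracks = tracks, strandings = strandings,
         otoliths = otoliths, diet = diet, main_prey = main,
         range_model = range_model, fields = fields,
         buffers = buffers_all, observations = observations,
         fits = fits, dic = dic, config = config,
         config_hash = hash(config)),
    class = "msfr_pipeline"
  )
}

#' @export
print.msfr_pipeline <- function(x, ...) {
  cat("MSFR pipeline result\n")
  cat("  main prey:", paste(x$main_prey, collapse = ", "), "\n")
  cat("  config hash:", x$config_hash, "\n")
  cat("  DIC comparison:\n")
  print(x$dic)
  invisible(x)
}
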