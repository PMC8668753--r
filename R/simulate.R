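# Synthetic-data generators: every input table the pipeline consumes can be
# drawn from a known ground truth, so each stage (and the whole pipeline)
# has a recoverable target.

#' Simulate bottom-trawl survey hauls
#'
#' Hauls are placed at random sea cells; for each haul, species and length
#' class, CPUE is drawn log-normally around the true prey surface:
#' `CPUE ~ logN(log(1 + S * w_L), sigma_log)`, where `S` is the surface
#' value at the haul and `w_L` the species' length-class weight. With a
#' zero-amplitude surface the draws therefore have median 1, and for large
#' `S` the mean CPUE is proportional to the surface amplitude. Only length
#' classes below 400 mm (sizes consumable by the predator) are generated.
#'
#' @param gt A [ground_truth()] object.
#' @param grid A [study_grid()].
#' @param n_hauls Number of hauls (>= 1).
#' @param years Integer vector of survey years.
#' @param quarters Survey quarters, subset of `c("Q1", "Q3")`.
#' @param sigma_log Log-scale SD of catch noise.
#' @param seed Optional integer seed (set via [set.seed()]).
#' @return A tibble with one row per haul x species x length class:
#'   `haul_id`, `lon`, `lat`, `depth_m`, `year`, `quarter`, `species`,
#'   `length_class_lower_mm`, `cpue`.
#' @export
sim_prey_surveys <- function(gt, grid, n_hauls, years = gt$ssb$year,
                             quarters = c("Q1", "Q3"),
                             sigma_log = 0.7, seed = NULL) {
  stopifnot(inherits(gt, "msfr_ground_truth"), n_hauls >= 1)
  if (!is.null(seed)) set.seed(seed)
  sea <- grid[grid$is_sea, ]
  if (nrow(sea) == 0) abort("study grid has an empty sea mask")

  idx <- sample.int(nrow(sea), n_hauls, replace = TRUE)
  hauls <- tibble(
    haul_id = seq_len(n_hauls),
    x = sea$x[idx], y = sea$y[idx],
    lon = sea$lon[idx], lat = sea$lat[idx],
    depth_m = sea$depth_m[idx],
    year = sample(years, n_hauls, replace = TRUE),
    quarter = sample(quarters, n_hauls, replace = TRUE)
  )

  classes <- length_classes(gt)
  out <- crossing(hauls, classes)
  surf <- numeric(nrow(out))
  for (grp in split(seq_len(nrow(out)),
                    paste(out$species, out$quarter, out$year))) {
    r <- out[grp[1], ]
    surf[grp] <- true_surface(gt, r$species, r$quarter, r$year,
                              out$x[grp], out$y[grp])
  }
  out$cpue <- rlnorm(nrow(out), meanlog = log1p(surf * out$class_weight),
                     sdlog = sigma_log)
  out |>
    select("haul_id", "lon", "lat", "depth_m", "year", "quarter",
           "species", length_class_lower_mm = "length_lower", "cpue")
}

# Per-species survey length classes (< 400 mm) and their relative weights.
length_classes <- function(gt) {
  gt$species_pars |>
    mutate(cls = map2(.data$typical_length_mm, .data$lw_e, function(tl, e) {
      lower <- tl + e * (-3:2)
      lower <- lower[lower >= e & lower < 400]
      w <- dnorm(seq_along(lower), mean = (length(lower) + 1) / 2, sd = 1.5)
      tibble(length_lower = lower, class_weight = w / sum(w))
    })) |>
    select("species", "cls") |>
    unnest("cls")
}

#' Simulate telemetry tracks as confined correlated random walks
#'
#' Each animal performs a correlated random walk on the projected grid with
#' gamma step lengths and persistent headings, rejected off the sea mask.
#' The log step-length scale depends on age class and sex through the same
#' coefficients that drive the ground truth's foraging-range model, so the
#' downstream range analysis has signal to detect.
#'
#' @param gt A [ground_truth()] object.
#' @param grid A [study_grid()].
#' @param n_animals Number of tagged animals (>= 1).
#' @param days Tracking duration per animal.
#' @param step_hours Time step of the walk in hours.
#' @param step_scale_km Baseline mean step length (km per step) for an
#'   adult female; set 0 for a degenerate stationary walk.
#' @param heading_sd SD (radians) of the heading increment.
#' @param start_date First possible deployment date.
#' @param seed Optional integer seed.
#' @return A tibble `animal_id`, `timestamp`, `lon`, `lat`, `age_class`,
#'   `sex`.
#' @export
sim_tracks <- function(gt, grid, n_animals, days = 60, step_hours = 2,
                       step_scale_km = 2.5, heading_sd = 0.6,
                       start_date = as.Date("2010-01-01"), seed = NULL) {
  stopifnot(inherits(gt, "msfr_ground_truth"), n_animals >= 1)
  if (!is.null(seed)) set.seed(seed)
  sea <- grid[grid$is_sea, ]
  cf <- gt$range_coefs
  n_steps <- ceiling(days * 24 / step_hours)
  center <- attr(grid, "center")
  xl <- attr(grid, "xlim"); yl <- attr(grid, "ylim")

  animals <- tibble(
    animal_id = sprintf("A%03d", seq_len(n_animals)),
    age_class = sample(c("juvenile", "adult"), n_animals, TRUE,
                       prob = c(0.7, 0.3)),
    sex = sample(c("F", "M"), n_animals, TRUE),
    t0 = start_date + sample.int(330, n_animals, replace = TRUE)
  )

  tracks <- pmap(animals, function(animal_id, age_class, sex, t0) {
    sc <- step_scale_km *
      exp(cf[["age_classjuvenile"]] * (age_class == "juvenile") +
            cf[["sexM"]] * (sex == "M"))
    start <- sea[sample.int(nrow(sea), 1), ]
    xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
    xs[1] <- start$x; ys[1] <- start$y
    heading <- runif(1, 0, 2 * pi)
    for (i in seq_len(n_steps)) {
      placed <- FALSE
      h <- heading + rnorm(1, 0, heading_sd)
      for (try in 1:25) {
        len <- if (sc > 0) rgamma(1, shape = 2, scale = sc / 2) else 0
        xn <- xs[i] + len * cos(h); yn <- ys[i] + len * sin(h)
        if (is_sea_at(grid, xn, yn)) { placed <- TRUE; break }
        h <- runif(1, 0, 2 * pi)
      }
      if (!placed) { xn <- xs[i]; yn <- ys[i] } else heading <- h
      xs[i + 1] <- xn; ys[i + 1] <- yn
    }
    ll <- unproj_aeqd(xs, ys, center)
    tibble(
      animal_id = animal_id,
      timestamp = as.POSIXct(t0, tz = "UTC") +
        seq(0, n_steps) * step_hours * 3600,
      lon = ll$lon, lat = ll$lat, age_class = age_class, sex = sex
    )
  })
  list_rbind(tracks)
}

# TRUE where (x, y) falls on a sea cell of the grid.
is_sea_at <- function(grid, x, y) {
  cell <- attr(grid, "cell_km")
  xl <- attr(grid, "xlim"); yl <- attr(grid, "ylim")
  nx <- round(diff(xl) / cell)
  ix <- floor((x - xl[1]) / cell) + 1
  iy <- floor((y - yl[1]) / cell) + 1
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= round(diff(yl) / cell)
  out <- logical(length(x))
  id <- (iy[ok] - 1) * nx + ix[ok]
  out[ok] <- grid$is_sea[id]
  out
}

#' Simulate foraging-range windows directly from the gamma GLM
#'
#' Draws covariates uniformly and MEC diameters from the gamma distribution
#' implied by the log-link coefficients, bypassing track simulation; the
#' direct fixture for parameter-recovery checks of [fit_range_glm()].
#'
#' @param n Number of windows.
#' @param coefs Named coefficient vector (see [default_range_coefs()]).
#' @param dispersion Gamma dispersion (squared coefficient of variation).
#' @param seed Optional integer seed.
#' @return A tibble `diameter_km`, `timeframe`, `age_class`, `sex`,
#'   `quarter` (factors where the model expects factors).
#' @export
sim_range_windows <- function(n, coefs = default_range_coefs(),
                              dispersion = 0.16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- tibble(
    timeframe = factor(sample(c(2, 4, 6, 8), n, TRUE), levels = c(2, 4, 6, 8)),
    age_class = factor(sample(c("adult", "juvenile"), n, TRUE),
                       levels = c("adult", "juvenile")),
    sex = factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M")),
    quarter = factor(sample(paste0("Q", 1:4), n, TRUE),
                     levels = paste0("Q", 1:4))
  )
  X <- stats::model.matrix(~ timeframe + age_class + sex + quarter, w)
  missing <- setdiff(colnames(X), names(coefs))
  if (length(missing)) abort(paste("missing coefficients:",
                                   paste(missing, collapse = ", ")))
  mu <- exp(drop(X %*% coefs[colnames(X)]))
  w |>
    mutate(diameter_km = rgamma(n, shape = 1 / dispersion,
                                rate = 1 / (dispersion * mu)),
           .before = 1)
}

#' Simulate strandings and stomach contents from the true response
#'
#' For each stranding the generator: places the carcass on the coastline
#' and draws a date, age class, sex and decomposition code (1-5, so the
#' freshness filter is exercised); computes the true foraging buffer from
#' the ground-truth range GLM; integrates the true prey surfaces (and the
#' SSB series for the reference species) over the buffer; rescales
#' availabilities to max 100 and forms the true diet proportions
#' `p_i = a_i B_i^m / sum_j a_j B_j^m`; draws a Poisson number of prey
#' items allocated multinomially so that expected mass shares equal `p_i`;
#' and emits otolith records by inverting the otolith-mass allometry, with
#' uniform wear grades. With `gt$length_sd = 0` the reconstruction in
#' [reconstruct_prey_mass()] is exactly invertible.
#'
#' @param gt A [ground_truth()] object.
#' @param grid A [study_grid()].
#' @param n_strandings Number of stranded individuals.
#' @param years Years to draw stranding dates from.
#' @param timeframe_days Foraging-range timeframe used for the true buffer.
#' @param seed Optional integer seed.
#' @return A list with tibbles `strandings` (`stranding_id`, `date`, `lon`,
#'   `lat`, `age_class`, `sex`, `decomposition_code`), `otoliths`
#'   (`stranding_id`, `species`, `otolith_length_mm`, `wear_grade`,
#'   `count`) and `truth` (`stranding_id`, `species`, `availability`,
#'   `true_prop`).
#' @export
sim_strandings <- function(gt, grid, n_strandings, years = gt$ssb$year,
                           timeframe_days = 4, seed = NULL) {
  stopifnot(inherits(gt, "msfr_ground_truth"), n_strandings >= 1)
  if (!is.null(seed)) set.seed(seed)
  yl <- attr(grid, "ylim"); center <- attr(grid, "center")
  sp <- gt$species_pars
  cf <- gt$range_coefs

  y <- runif(n_strandings, yl[1] + 15, yl[2] - 15)
  x <- coast_easting(grid, y) - 0.5
  ll <- unproj_aeqd(x, y, center)
  yr <- sample(years, n_strandings, replace = TRUE)
  date <- as.Date(sprintf("%d-01-01", yr)) +
    sample.int(364, n_strandings, replace = TRUE) - 1
  strand <- tibble(
    stranding_id = sprintf("S%04d", seq_len(n_strandings)),
    date = date, lon = ll$lon, lat = ll$lat, x = x, y = y, year = yr,
    age_class = sample(c("juvenile", "adult"), n_strandings, TRUE,
                       prob = c(0.75, 0.25)),
    sex = sample(c("F", "M"), n_strandings, TRUE),
    decomposition_code = sample(1:5, n_strandings, TRUE,
                                prob = gt$decomp_probs)
  )

  # true buffer radius = true predicted MEC diameter (km)
  radius <- exp(
    cf[["(Intercept)"]] +
      unname(c(`2` = 0, `4` = cf[["timeframe4"]], `6` = cf[["timeframe6"]],
               `8` = cf[["timeframe8"]])[as.character(timeframe_days)]) +
      cf[["age_classjuvenile"]] * (strand$age_class == "juvenile") +
      cf[["sexM"]] * (strand$sex == "M") +
      dplyr::case_match(calendar_quarter(strand$date),
                        "Q2" ~ cf[["quarterQ2"]], "Q3" ~ cf[["quarterQ3"]],
                        "Q4" ~ cf[["quarterQ4"]], .default = 0)
  )

  B <- matrix(0, n_strandings, nrow(sp),
              dimnames = list(strand$stranding_id, sp$species))
  season <- assign_season(strand$date)
  for (i in seq_len(n_strandings)) {
    cells <- cells_in_circle(grid, strand$x[i], strand$y[i], radius[i])
    for (s in sp$species[-1]) {
      B[i, s] <- sum(true_surface(gt, s, season[i], strand$year[i],
                                  cells$x, cells$y))
    }
    B[i, sp$species[1]] <- gt$ssb$ssb[match(strand$year[i], gt$ssb$year)]
  }
  if (all(B == 0)) abort("all true availabilities are zero")
  B <- if (gt$availability_scale == "per_species") {
    sweep(B, 2, apply(B, 2, max) / 100, "/")
  } else {
    B / max(B) * 100
  }

  P <- msfr_proportions(setNames(sp$attack_rate, sp$species), B, gt$shape_m)

  mbar <- sp$lw_a * ((sp$typical_length_mm + 0.5 * sp$lw_e) / 10)^sp$lw_b
  oto <- map(seq_len(n_strandings), function(i) {
    n_items <- rpois(1, gt$mean_items) + 1
    q <- P[i, ] / mbar
    counts <- drop(rmultinom(1, n_items, q / sum(q)))
    rows <- map(which(counts > 0), function(j) {
      w <- mbar[j] * exp(rnorm(counts[j], -gt$length_sd^2 / 2, gt$length_sd))
      corrected <- (w / sp$oto_a[j])^(1 / sp$oto_b[j])
      g <- sample(gt$grades$grade, counts[j], replace = TRUE)
      tibble(
        stranding_id = strand$stranding_id[i],
        species = sp$species[j],
        otolith_length_mm = corrected /
          gt$grades$factor[match(g, gt$grades$grade)],
        wear_grade = g
      )
    })
    list_rbind(rows)
  }) |> list_rbind()

  oto <- oto |>
    mutate(otolith_length_mm = round(.data$otolith_length_mm, 6)) |>
    count(.data$stranding_id, .data$species, .data$otolith_length_mm,
          .data$wear_grade, name = "count")

  truth <- tibble(
    stranding_id = rep(strand$stranding_id, each = ncol(B)),
    species = rep(colnames(B), n_strandings),
    availability = as.vector(t(B)),
    true_prop = as.vector(t(P))
  )

  list(
    strandings = select(strand, "stranding_id", "date", "lon", "lat",
                        "age_class", "sex", "decomposition_code"),
    otoliths = oto,
    truth = truth
  )
}

#' Simulate diet observations directly from the functional response
#'
#' The direct fixture for [fit_msfr()]: availabilities are drawn uniformly
#' per individual and species, true proportions follow the response, and
#' observed proportions are Dirichlet around them with concentration `tau`.
#'
#' @param n Number of individuals.
#' @param attack_rates Named positive vector; first element is the
#'   reference species (attack rate need not be 1 here, only ratios
#'   matter, but recovery tests fix it at 1).
#' @param shape_m Response shape.
#' @param tau Dirichlet concentration of observed diet around the truth.
#' @param avail_range Range of the uniform availability draw (index scale,
#'   max 100 as in the fitting convention).
#' @param avail_cv CV attached as the reported availability SD.
#' @param seed Optional integer seed.
#' @return A long tibble `stranding_id`, `species`, `prop`, `avail_mean`,
#'   `avail_sd` with the generative parameters in attributes `attack_rates`
#'   and `shape_m`.
#' @export
sim_diet_observations <- function(n, attack_rates, shape_m, tau = 50,
                                  avail_range = c(5, 100), avail_cv = 0.05,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(attack_rates)
  species <- names(attack_rates)
  if (is.null(species)) abort("`attack_rates` must be named")
  B <- matrix(runif(n * S, avail_range[1], avail_range[2]), n, S,
              dimnames = list(NULL, species))
  P <- msfr_proportions(attack_rates, B, shape_m)
  G <- matrix(rgamma(n * S, shape = tau * P), n, S)
  obs <- G / rowSums(G)
  out <- tibble(
    stranding_id = rep(sprintf("S%04d", seq_len(n)), each = S),
    species = rep(species, n),
    prop = as.vector(t(obs)),
    avail_mean = as.vector(t(B)),
    avail_sd = avail_cv * as.vector(t(B))
  )
  attr(out, "attack_rates") <- attack_rates
  attr(out, "shape_m") <- shape_m
  out
}

#' Write the synthetic input tables (and optional truth table) to CSV
#'
#' @param hauls,tracks,strandings,otoliths Tibbles from the generators.
#' @param truth Optional truth tibble from [sim_strandings()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_tables <- function(hauls, tracks, strandings, otoliths,
                                   truth = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(hauls = hauls, tracks = tracks, strandings = strandings,
               otoliths = otoliths)
  if (!is.null(truth)) tabs$ground_truth <- truth
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tabs[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
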