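# Prey availability: survey catches to biomass-per-unit-effort, penalised
# spatial smoothing, buffer integration with parametric coefficient
# resampling, an SSB-based index for poorly surveyed species, and the
# max-100 rescaling.

#' Convert catch-at-length to biomass per unit effort
#'
#' For each haul and species, `BPUE = sum_L a * ((L + 0.5 e) / 10)^b *
#' CPUE_L` over length classes with lower limit `L < 400` mm: per-fish
#' mass from the class-midpoint length (mm converted to cm) via the
#' species' length-weight parameters, weighted by catch per unit effort.
#' Sizes of 400 mm and above are not consumable by the predator and are
#' excluded.
#'
#' @param hauls Tibble with `haul_id`, `lon`, `lat`, `depth_m`, `year`,
#'   `quarter`, `species`, `length_class_lower_mm`, `cpue`.
#' @param lw Tibble `species`, `lw_a`, `lw_b`, `lw_e` (length resolution
#'   in mm, 5 or 10 depending on species).
#' @return A tibble with one row per haul x species and a `bpue_g` column
#'   (haul covariates carried through).
#' @export
#' @examples
#' h <- tibble::tibble(haul_id = 1, lon = 4, lat = 54, depth_m = 30,
#'                     year = 2010, quarter = "Q1", species = "whiting",
#'                     length_class_lower_mm = 100, cpue = 2)
#' lw <- tibble::tibble(species = "whiting", lw_a = 0.01, lw_b = 3, lw_e = 10)
#' compute_bpue(h, lw)  # 2 * 0.01 * 10.5^3 = 23.1525 g
compute_bpue <- function(hauls, lw) {
  missing <- setdiff(unique(hauls$species), lw$species)
  if (length(missing)) {
    abort(paste0("no length-weight parameters for: ",
                 paste(missing, collapse = ", ")))
  }
  hauls |>
    left_join(lw, by = "species") |>
    filter(.data$length_class_lower_mm < 400) |>
    mutate(fish_mass_g = .data$lw_a *
             ((.data$length_class_lower_mm + 0.5 * .data$lw_e) / 10)^.data$lw_b) |>
    group_by(.data$haul_id, .data$lon, .data$lat, .data$depth_m,
             .data$year, .data$quarter, .data$species) |>
    summarise(bpue_g = sum(.data$fish_mass_g * .data$cpue),
              .groups = "drop")
}

#' Fit a spatio-temporal prey-density field
#'
#' Penalised regression on `log(BPUE + delta)` with a univariate depth
#' smooth plus a three-dimensional tensor-product smooth of projected
#' easting, northing and year, Gaussian errors, and smoothing parameters
#' chosen by REML (or GCV). Predictions are made on the sea cells of the
#' study grid for every year in the data; the coefficient covariance is
#' retained for parametric resampling of buffer integrals. Land cells are
#' masked out of the prediction (they carry no basis-evaluation points and
#' receive no prediction).
#'
#' @param bpue Output of [compute_bpue()] for one species and quarter (at
#'   least 100 records spanning at least 2 years).
#' @param grid A [study_grid()] providing the prediction cells and the
#'   projection.
#' @param k_space Basis dimension of the spatial margin of the tensor
#'   product.
#' @param k_year,k_depth Basis dimensions for year and depth smooths.
#' @param delta Offset added before the log transform (g); guards zero
#'   catches.
#' @param method Smoothing-parameter criterion, `"REML"` (default) or
#'   `"GCV.Cp"`.
#' @return An object of class `prey_field`: list with the `gam` fit, the
#'   species/quarter labels, the prediction tibble `grid_pred` (`cell_id`,
#'   `x`, `y`, `year`, `eta` on the log scale, `bpue` back-transformed as
#'   `exp(eta)`), `delta`, and the projection centre.
#' @export
fit_prey_field <- function(bpue, grid, k_space = 5, k_year = 4, k_depth = 5,
                           delta = 1, method = "REML") {
  if (nrow(bpue) < 100) warn("fewer than 100 records: smooth will be weak")
  if (length(unique(bpue$year)) < 2) {
    abort("prey-field smoothing needs records from at least 2 years")
  }
  species <- unique(bpue$species)
  quarter <- unique(bpue$quarter)
  if (length(species) != 1 || length(quarter) != 1) {
    abort("fit one prey field per species and quarter")
  }
  center <- attr(grid, "center")
  xy <- proj_aeqd(bpue$lon, bpue$lat, center)
  d <- tibble(log_bpue = log(bpue$bpue_g + delta),
              x = xy$x, y = xy$y, depth_m = bpue$depth_m, year = bpue$year)

  # the year margin needs at least 3 distinct years for a spline basis;
  # with fewer, year enters as a linear trend alongside the spatial smooth
  n_years <- length(unique(d$year))
  form <- if (n_years >= 3) {
    k_year <- min(k_year, n_years)
    log_bpue ~ s(depth_m, k = k_depth) +
      te(x, y, year, d = c(2, 1), k = c(k_space, k_year))
  } else {
    log_bpue ~ s(depth_m, k = k_depth) + te(x, y, k = k_space) + year
  }
  fit <- mgcv::gam(form, data = d, method = method)

  years <- sort(unique(d$year))
  sea <- grid[grid$is_sea, c("cell_id", "x", "y", "depth_m")]
  newd <- crossing(sea, year = years)
  eta <- as.numeric(predict(fit, newdata = newd))
  if (any(!is.finite(eta))) abort("non-finite prey-field prediction on sea cells")
  grid_pred <- mutate(newd, eta = eta, bpue = exp(eta))

  structure(
    list(fit = fit, species = species, quarter = quarter,
         grid_pred = grid_pred, delta = delta, center = center,
         cell_km = attr(grid, "cell_km")),
    class = "prey_field"
  )
}

#' @export
print.prey_field <- function(x, ...) {
  cat(sprintf("Prey field: %s, %s (%d cells x %d years)\n", x$species,
              x$quarter, length(unique(x$grid_pred$cell_id)),
              length(unique(x$grid_pred$year))))
  cat(sprintf("  deviance explained: %.1f%%\n",
              100 * summary(x$fit)$dev.expl))
  invisible(x)
}

#' @export
glance.prey_field <- function(x, ...) {
  s <- summary(x$fit)
  tibble(species = x$species, quarter = x$quarter,
         dev_explained = s$dev.expl, n = stats::nobs(x$fit),
         edf = sum(x$fit$edf))
}

#' Integrate a prey field over a foraging buffer
#'
#' Sums the back-transformed predicted density over the sea cells whose
#' centres fall inside the buffer circle, for the buffer's year. The SD is
#' obtained by parametric resampling: coefficient vectors are drawn from
#' the fitted smoother's covariance, the cell sum recomputed per draw, and
#' the SD taken over draws.
#'
#' @param field A [fit_prey_field()] object.
#' @param buffer One row of a [predict_buffer()] tibble (needs `lon`,
#'   `lat`, `radius_km`) plus a `year` (passed separately).
#' @param year Year at which to evaluate the field.
#' @param n_draws Number of coefficient draws for the SD.
#' @param seed Optional integer seed.
#' @return A list `mean`, `sd`, `n_cells`.
#' @export
integrate_buffer <- function(field, buffer, year, n_draws = 200,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  yrs <- unique(field$grid_pred$year)
  year_use <- yrs[which.min(abs(yrs - year))]
  ctr <- proj_aeqd(buffer$lon, buffer$lat, field$center)
  cells <- field$grid_pred |>
    filter(.data$year == year_use,
           (.data$x - ctr$x)^2 + (.data$y - ctr$y)^2 <= buffer$radius_km^2)
  if (nrow(cells) == 0) {
    abort("buffer contains no sea cells (entirely on land or outside grid)")
  }
  m <- sum(cells$bpue)

  Vp <- if (n_draws > 0) vcov(field$fit) else matrix(0, 0, 0)
  if (n_draws > 0 && any(Vp != 0)) {
    Xp <- predict(field$fit,
                  newdata = mutate(cells, depth_m = .data$depth_m,
                                   year = year_use),
                  type = "lpmatrix")
    beta <- MASS::mvrnorm(n_draws, coef(field$fit), Vp)
    sums <- colSums(exp(Xp %*% t(beta)))
    s <- sd(sums)
  } else {
    s <- 0
  }
  list(mean = m, sd = s, n_cells = nrow(cells))
}

#' Availability index for a species indexed by spawning-stock biomass
#'
#' For species poorly sampled by the survey, availability is taken as the
#' annual SSB estimate: spatially constant within a year, identical for
#' all strandings of that year. The SD is `cv * mean` (default CV 0).
#'
#' @param ssb Tibble `year`, `ssb`.
#' @param year Stranding year(s).
#' @param cv Coefficient of variation attached to the index.
#' @return A tibble `year`, `mean`, `sd`.
#' @export
sandeel_availability <- function(ssb, year, cv = 0) {
  i <- match(year, ssb$year)
  if (anyNA(i)) {
    abort(paste0("no SSB estimate for year(s): ",
                 paste(unique(year[is.na(i)]), collapse = ", ")))
  }
  tibble(year = year, mean = ssb$ssb[i], sd = cv * ssb$ssb[i])
}

#' Estimate per-stranding, per-species prey availability
#'
#' Integrates each fitted prey field over each stranding's foraging buffer
#' (matching the stranding's survey season to the field's quarter) and
#' adds the SSB-based index for the reference species, then rescales so
#' the maximum availability is 100.
#'
#' @param fields Named list of [fit_prey_field()] objects, names
#'   `"species.quarter"` (e.g. `"whiting.Q1"`).
#' @param buffers [predict_buffer()] output joined with `year` and
#'   `season_quarter` columns.
#' @param ssb Tibble `year`, `ssb` for the reference species (or NULL).
#' @param ref_species Name of the SSB-indexed species.
#' @param ssb_cv CV for the SSB index.
#' @param n_draws Coefficient draws per buffer integral.
#' @param scale Passed to [rescale_availability()].
#' @param seed Optional integer seed.
#' @return An availability tibble `stranding_id`, `species`, `mean`, `sd`,
#'   rescaled to max 100.
#' @export
estimate_availability <- function(fields, buffers, ssb = NULL,
                                  ref_species = "sandeel", ssb_cv = 0,
                                  n_draws = 200,
                                  scale = c("global", "per_species"),
                                  seed = NULL) {
  scale <- match.arg(scale)
  if (!is.null(seed)) set.seed(seed)
  rows <- map(seq_len(nrow(buffers)), function(i) {
    b <- buffers[i, ]
    sp_rows <- map(fields, function(f) {
      if (f$quarter != b$season_quarter) return(NULL)
      est <- integrate_buffer(f, b, year = b$year, n_draws = n_draws)
      tibble(stranding_id = b$stranding_id, species = f$species,
             mean = est$mean, sd = est$sd)
    })
    list_rbind(sp_rows[!vapply(sp_rows, is.null, TRUE)])
  }) |> list_rbind()
  if (!is.null(ssb)) {
    sa <- sandeel_availability(ssb, buffers$year, cv = ssb_cv)
    rows <- bind_rows(rows, tibble(
      stranding_id = buffers$stranding_id, species = ref_species,
      mean = sa$mean, sd = sa$sd
    ))
  }
  rescale_availability(rows, scale = scale)
}

#' Rescale availabilities so the maximum is 100
#'
#' Divides means and SDs by `max(mean) / 100` — either one global factor
#' (preserving cross-species ratios, the default) or one factor per
#' species (each species' maximum becomes 100, matching the
#' per-species-index interpretation of attack rates). Idempotent; ratios
#' within the chosen scaling unit are preserved exactly.
#'
#' @param avail Tibble with `species`, `mean`, `sd`.
#' @param scale `"global"` or `"per_species"`.
#' @return The rescaled tibble.
#' @export
#' @examples
#' rescale_availability(tibble::tibble(species = "a", mean = c(5, 10, 20),
#'                                     sd = c(1, 2, 4)))
rescale_availability <- function(avail, scale = c("global", "per_species")) {
  scale <- match.arg(scale)
  if (all(avail$mean == 0)) abort("all availabilities are zero")
  if (scale == "global") {
    f <- max(avail$mean) / 100
    mutate(avail, mean = .data$mean / f, sd = .data$sd / f)
  } else {
    avail |>
      group_by(.data$species) |>
      mutate(f = max(max(.data$mean) / 100, .Machine$double.xmin),
             mean = .data$mean / .data$f, sd = .data$sd / .data$f) |>
      ungroup() |>
      select(-"f")
  }
}
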