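# Foraging range from telemetry: regional filtering, track regularisation,
# minimum-enclosing-circle windows, a gamma GLM for window diameter, and
# per-stranding circular buffers.

#' Exclude telemetry positions outside the study region
#'
#' Removes positions in the inner waters (south of `lat_max` AND east of
#' `lon_min`); everything else is kept. The defaults drop the southern
#' Kattegat and waters further south-east, retaining movements
#' representative of the open shelf sea.
#'
#' @param track Tibble with `lon` and `lat`.
#' @param lat_max,lon_min Exclusion thresholds in decimal degrees.
#' @return The filtered tibble.
#' @export
#' @examples
#' filter_region(tibble::tibble(lon = c(9.5, 9.5, 9.0),
#'                              lat = c(57.4, 57.2, 57.2)))
filter_region <- function(track, lat_max = 57.30, lon_min = 9.37) {
  track[!(track$lat < lat_max & track$lon > lon_min), , drop = FALSE]
}

#' Resample a track to regular time intervals
#'
#' Positions are linearly interpolated in projected coordinates at a fixed
#' step; gaps longer than `max_gap_hours` split the track into segments so
#' no interpolation bridges a transmission gap.
#'
#' @param track Tibble with `animal_id`, `timestamp` (POSIXct), `lon`,
#'   `lat` and optional covariate columns (carried through per animal).
#' @param step_hours Interpolation step (hours).
#' @param max_gap_hours Gaps longer than this start a new segment.
#' @param center Projection centre `c(lon, lat)`; defaults to the track
#'   centroid.
#' @return A tibble `animal_id`, `segment`, `timestamp`, `x`, `y`, `lon`,
#'   `lat` plus carried covariates.
#' @export
regularize_track <- function(track, step_hours = 6, max_gap_hours = 24,
                             center = c(mean(track$lon), mean(track$lat))) {
  stopifnot(nrow(track) >= 2)
  covars <- setdiff(names(track), c("timestamp", "lon", "lat", "x", "y",
                                    "segment"))
  out <- track |>
    group_by(.data$animal_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::group_map(function(d, key) {
      if (any(diff(as.numeric(d$timestamp)) <= 0)) {
        abort(sprintf("non-increasing timestamps for animal %s",
                      key$animal_id))
      }
      xy <- proj_aeqd(d$lon, d$lat, center)
      t_num <- as.numeric(d$timestamp)
      gaps <- c(0, diff(t_num)) > max_gap_hours * 3600
      seg <- cumsum(gaps) + 1
      segs <- map(split(seq_len(nrow(d)), seg), function(ii) {
        if (length(ii) < 2) return(NULL)
        tt <- seq(t_num[ii[1]], t_num[ii[length(ii)]], by = step_hours * 3600)
        tibble(
          animal_id = key$animal_id,
          segment = seg[ii[1]],
          timestamp = as.POSIXct(tt, tz = "UTC",
                                 origin = "1970-01-01"),
          x = stats::approx(t_num[ii], xy$x[ii], tt)$y,
          y = stats::approx(t_num[ii], xy$y[ii], tt)$y
        )
      })
      res <- list_rbind(segs[!vapply(segs, is.null, TRUE)])
      for (cv in setdiff(covars, "animal_id")) res[[cv]] <- d[[cv]][1]
      res
    }) |>
    list_rbind()
  ll <- unproj_aeqd(out$x, out$y, center)
  out$lon <- ll$lon; out$lat <- ll$lat
  attr(out, "center") <- center
  out
}

#' Minimum-enclosing-circle windows along a regular track
#'
#' Slices each track segment into consecutive (non-overlapping by default)
#' windows of `timeframe_days` and computes the MEC of the positions in
#' each window. Windows with fewer than 2 positions are skipped with a
#' message. The window's season covariate is the calendar quarter of its
#' midpoint.
#'
#' @param regtrack Output of [regularize_track()].
#' @param timeframe_days Window length in days (2, 4, 6 or 8 in the
#'   standard analysis).
#' @param stride_days Window stride; defaults to `timeframe_days`
#'   (non-overlapping, limiting pseudo-replication).
#' @return A tibble `animal_id`, `window_start`, `timeframe`,
#'   `diameter_km`, `center_x`, `center_y`, `n_positions`, `quarter` plus
#'   carried covariates (`age_class`, `sex`, ...).
#' @export
build_mec_windows <- function(regtrack, timeframe_days,
                              stride_days = timeframe_days) {
  stopifnot(timeframe_days > 0, stride_days > 0)
  covars <- intersect(c("age_class", "sex"), names(regtrack))
  skipped <- 0L
  out <- regtrack |>
    group_by(.data$animal_id, .data$segment) |>
    dplyr::group_map(function(d, key) {
      t0 <- min(d$timestamp)
      starts <- seq(from = 0,
                    to = max(0, as.numeric(difftime(max(d$timestamp), t0,
                                                    units = "days"))),
                    by = stride_days)
      rows <- map(starts, function(s) {
        in_win <- d$timestamp >= t0 + s * 86400 &
          d$timestamp < t0 + (s + timeframe_days) * 86400
        if (sum(in_win) < 2) { skipped <<- skipped + 1L; return(NULL) }
        mec <- minimum_enclosing_circle(d$x[in_win], d$y[in_win])
        mid <- t0 + (s + timeframe_days / 2) * 86400
        r <- tibble(
          animal_id = key$animal_id,
          window_start = t0 + s * 86400,
          timeframe = factor(timeframe_days, levels = c(2, 4, 6, 8)),
          diameter_km = 2 * mec$radius,
          center_x = mec$center[1], center_y = mec$center[2],
          n_positions = sum(in_win),
          quarter = factor(calendar_quarter(as.Date(mid)),
                           levels = paste0("Q", 1:4))
        )
        for (cv in covars) r[[cv]] <- d[[cv]][1]
        r
      })
      list_rbind(rows[!vapply(rows, is.null, TRUE)])
    }) |>
    list_rbind()
  if (skipped > 0) {
    inform(sprintf("build_mec_windows: skipped %d window(s) with < 2 positions",
                   skipped))
  }
  out
}

#' Fit the foraging-range model (gamma GLM, log link)
#'
#' Models MEC diameter as gamma-distributed with a log link in timeframe,
#' age class, sex and quarter; starting from the main-effects model, a
#' stepwise AIC search over all two-way interactions selects the final
#' model. Variance inflation factors are computed on the main-effects
#' design and terms exceeding `vif_threshold` are flagged (and dropped
#' only when `drop_collinear = TRUE`).
#'
#' @param windows Window tibble with `diameter_km`, `timeframe`,
#'   `age_class`, `sex`, `quarter`. Non-positive diameters (stationary
#'   windows) are dropped with a warning.
#' @param interactions Search two-way interactions by stepwise AIC?
#' @param vif_threshold Collinearity flag threshold.
#' @param drop_collinear Drop flagged terms before the interaction search?
#' @return An object of class `range_model`: list with the fitted `glm`,
#'   `vif` table, `flagged` terms, `aic`, and the factor levels seen.
#' @export
fit_range_glm <- function(windows, interactions = TRUE, vif_threshold = 4,
                          drop_collinear = FALSE) {
  if (nrow(windows) < 50) {
    warn("fewer than 50 windows: range-model estimates will be unstable")
  }
  if (any(windows$diameter_km <= 0)) {
    warn(sprintf("dropping %d window(s) with zero diameter",
                 sum(windows$diameter_km <= 0)))
    windows <- windows[windows$diameter_km > 0, , drop = FALSE]
  }
  windows <- droplevels(as_tibble(windows))
  terms_main <- c("timeframe", "age_class", "sex", "quarter")
  terms_main <- terms_main[vapply(terms_main, function(v) {
    length(unique(windows[[v]])) > 1
  }, TRUE)]
  f0 <- if (length(terms_main)) {
    stats::reformulate(terms_main, response = "diameter_km")
  } else {
    diameter_km ~ 1
  }
  fit0 <- glm(f0, family = Gamma(link = "log"), data = windows)
  if (!fit0$converged) abort("gamma GLM did not converge (main effects)")

  vif_tab <- if (length(terms_main) > 1) {
    v <- car::vif(fit0)
    v <- if (is.matrix(v)) v[, 1] else v
    tibble(term = rownames(as.matrix(v)) %||% names(v), vif = as.numeric(v))
  } else {
    tibble(term = terms_main, vif = NA_real_)
  }
  flagged <- vif_tab$term[!is.na(vif_tab$vif) & vif_tab$vif > vif_threshold]
  if (length(flagged)) {
    warn(paste0("VIF > ", vif_threshold, " for: ",
                paste(flagged, collapse = ", ")))
    if (drop_collinear) {
      terms_main <- setdiff(terms_main, flagged)
      fit0 <- glm(stats::reformulate(terms_main, response = "diameter_km"),
                  family = Gamma(link = "log"), data = windows)
    }
  }

  fit <- if (interactions && length(terms_main) > 1) {
    upper <- as.formula(paste("~ (", paste(terms_main, collapse = " + "),
                              ")^2"))
    stats::step(fit0, scope = list(lower = f0, upper = upper),
                direction = "both", trace = 0)
  } else {
    fit0
  }
  if (!fit$converged) abort("gamma GLM did not converge")

  structure(
    list(fit = fit, vif = vif_tab, flagged = flagged, aic = AIC(fit),
         dispersion = summary(fit)$dispersion,
         levels = lapply(windows[terms_main], function(v) levels(factor(v)))),
    class = "range_model"
  )
}

#' @export
print.range_model <- function(x, ...) {
  cat("Foraging-range gamma GLM (log link)\n")
  cat("  formula:", deparse(formula(x$fit)), "\n")
  cat(sprintf("  AIC %.1f, dispersion %.4f\n", x$aic, x$dispersion))
  if (length(x$flagged)) {
    cat("  VIF-flagged terms:", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.range_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.range_model <- function(x, ...) {
  tibble(aic = x$aic, dispersion = x$dispersion,
         deviance = x$fit$deviance, null.deviance = x$fit$null.deviance,
         nobs = stats::nobs(x$fit),
         max_vif = suppressWarnings(max(x$vif$vif, na.rm = TRUE)))
}

#' Predicted-range table over all covariate combinations
#'
#' Mean predicted MEC diameter and its standard error for every
#' combination of timeframe, quarter, age class and sex seen in fitting;
#' the standard summary layout for a foraging-range model.
#'
#' @param model A [fit_range_glm()] object.
#' @return A tibble with the covariates, `diameter_km` and `se_km`.
#' @export
predict_range_table <- function(model) {
  grid <- do.call(crossing, lapply(model$levels, factor))
  pr <- predict(model$fit, newdata = grid, type = "response", se.fit = TRUE)
  bind_cols(grid, tibble(diameter_km = unname(pr$fit),
                         se_km = unname(pr$se.fit)))
}

#' Predict per-stranding foraging buffers
#'
#' The GLM-predicted MEC diameter for the stranding's covariates is used
#' directly as the radius of a circle centred on the stranding location
#' (the diameter-as-radius convention compensates for the buffer centre
#' lying on the coast rather than at sea). No further inflation is
#' applied.
#'
#' @param model A [fit_range_glm()] object.
#' @param strandings Tibble with `stranding_id`, `lon`, `lat`, `date`,
#'   `age_class`, `sex`.
#' @param timeframe_days Timeframe (must have been seen in fitting).
#' @return A `foraging_buffer` tibble: `stranding_id`, `lon`, `lat`,
#'   `radius_km`, `timeframe`.
#' @export
predict_buffer <- function(model, strandings, timeframe_days) {
  nd <- tibble(
    timeframe = factor(timeframe_days, levels = model$levels$timeframe),
    age_class = factor(strandings$age_class,
                       levels = model$levels$age_class),
    sex = factor(strandings$sex, levels = model$levels$sex),
    quarter = factor(calendar_quarter(strandings$date),
                     levels = model$levels$quarter)
  )
  nd <- nd[intersect(names(nd), names(model$levels))]
  if (anyNA(nd)) {
    abort("stranding covariates contain levels unseen when fitting the range model")
  }
  tibble(
    stranding_id = strandings$stranding_id,
    lon = strandings$lon, lat = strandings$lat,
    radius_km = unname(predict(model$fit, newdata = nd, type = "response")),
    timeframe = timeframe_days
  )
}
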