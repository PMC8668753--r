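# BPUE conversion, spatio-temporal smoothing, buffer integration and the
# max-100 rescaling.

make_hauls <- function(df) {
  dplyr::mutate(df, haul_id = dplyr::row_number(), lon = 4, lat = 54,
                depth_m = 30, year = 2010, quarter = "Q1")
}

test_that("BPUE follows the midpoint length-weight formula", {
  lw <- tibble::tibble(species = "whiting", lw_a = 0.01, lw_b = 3, lw_e = 10)
  h <- make_hauls(tibble::tibble(species = "whiting",
                                 length_class_lower_mm = 100, cpue = 2))
  # per fish: 0.01 * ((100 + 5)/10)^3 = 11.57625 g; times CPUE 2
  expect_equal(compute_bpue(h, lw)$bpue_g, 2 * 0.01 * 10.5^3)

  h0 <- make_hauls(tibble::tibble(species = "whiting",
                                  length_class_lower_mm = c(100, 200),
                                  cpue = 0)) |>
    dplyr::mutate(haul_id = 1)
  expect_equal(compute_bpue(h0, lw)$bpue_g, 0)

  # the 400 mm class is not consumable and is excluded; 395 mm is kept
  h4 <- make_hauls(tibble::tibble(species = "whiting",
                                  length_class_lower_mm = c(395, 400),
                                  cpue = 1))
  expect_equal(compute_bpue(h4, lw)$bpue_g, 0.01 * ((395 + 5) / 10)^3)

  expect_error(compute_bpue(
    make_hauls(tibble::tibble(species = "eel", length_class_lower_mm = 100,
                              cpue = 1)), lw), "eel")
})

sim_bpue <- function(n, f = function(x, y) 0, sd = 0.3, years = 2010:2011,
                     grid = test_grid(), seed = 1) {
  set.seed(seed)
  sea <- grid[grid$is_sea, ]
  i <- sample.int(nrow(sea), n, replace = TRUE)
  tibble::tibble(
    haul_id = seq_len(n), lon = sea$lon[i], lat = sea$lat[i],
    depth_m = sea$depth_m[i], year = sample(years, n, TRUE),
    quarter = "Q1", species = "whiting",
    bpue_g = exp(f(sea$x[i], sea$y[i]) + rnorm(n, 0, sd)) - 1
  ) |>
    dplyr::mutate(bpue_g = pmax(bpue_g, 0))
}

test_that("a flat surface is recovered as flat", {
  grid <- test_grid()
  b <- sim_bpue(400, f = function(x, y) 2, grid = grid, seed = 7)
  fld <- fit_prey_field(b, grid)
  expect_s3_class(fld, "prey_field")
  expect_true(all(fld$grid_pred$bpue > 0))

  # predictions should sit within 2 SEs of the overall mean at almost
  # every cell (null-signal recovery)
  pr <- predict(fld$fit, newdata = fld$grid_pred, se.fit = TRUE)
  dev <- abs(as.numeric(pr$fit) - mean(fld$grid_pred$eta))
  expect_gt(mean(dev <= 2 * as.numeric(pr$se.fit)), 0.9)

  g <- glance(fld)
  expect_true(g$dev_explained >= 0 && g$dev_explained <= 1)
})

test_that("field estimation is consistent as survey effort grows", {
  grid <- test_grid()
  bump <- function(x, y) 3 * exp(-((x + 40)^2 + y^2) / (2 * 60^2))
  ise <- vapply(c(200, 2000), function(n) {
    b <- sim_bpue(n, f = bump, grid = grid, seed = 11)
    fld <- fit_prey_field(b, grid)
    truth <- bump(fld$grid_pred$x, fld$grid_pred$y)
    mean((fld$grid_pred$eta - truth)^2)
  }, 0)
  expect_lt(ise[2], ise[1])
})

test_that("buffer integration sums cell predictions and propagates coefficient noise", {
  grid <- test_grid()
  b <- sim_bpue(500, f = function(x, y) 2 + 0.01 * x, grid = grid, seed = 3)
  fld <- fit_prey_field(b, grid)

  # uniform-field closed form: overwrite predictions with a constant
  fld_const <- fld
  fld_const$grid_pred$bpue <- 5
  buf <- tibble::tibble(stranding_id = "s1", lon = 3.2, lat = 54,
                        radius_km = 60)
  est <- integrate_buffer(fld_const, buf, year = 2010, n_draws = 0)
  expect_equal(est$mean, 5 * est$n_cells)
  expect_equal(est$sd, 0)

  # zero coefficient covariance forces a zero resampling SD
  fld0 <- fld
  fld0$fit$Vp[] <- 0
  est0 <- integrate_buffer(fld0, buf, year = 2010, n_draws = 50)
  expect_equal(est0$sd, 0)

  # monotone in radius for a non-negative field
  est_small <- integrate_buffer(fld, buf, year = 2010, n_draws = 0)
  buf_big <- dplyr::mutate(buf, radius_km = 100)
  est_big <- integrate_buffer(fld, buf_big, year = 2010, n_draws = 0)
  expect_gte(est_big$mean, est_small$mean)
  expect_gte(est_big$n_cells, est_small$n_cells)

  # entirely outside the grid
  far <- tibble::tibble(stranding_id = "s2", lon = 40, lat = 30,
                        radius_km = 5)
  expect_error(integrate_buffer(fld, far, year = 2010), "no sea cells")
})

test_that("resampling SD agrees with the delta method", {
  grid <- test_grid()
  b <- sim_bpue(600, f = function(x, y) 2 + 0.005 * x, grid = grid, seed = 9)
  fld <- fit_prey_field(b, grid)
  buf <- tibble::tibble(stranding_id = "s1", lon = 3.4, lat = 54.2,
                        radius_km = 80)

  est <- integrate_buffer(fld, buf, year = 2010, n_draws = 10000, seed = 2)

  # delta method: var(sum exp(X b)) ~ g' Vp g with g = X' exp(X b)
  ctr <- proj_aeqd(buf$lon, buf$lat, fld$center)
  cells <- dplyr::filter(fld$grid_pred, year == 2010,
                         (x - ctr$x)^2 + (y - ctr$y)^2 <= buf$radius_km^2)
  Xp <- predict(fld$fit, newdata = cells, type = "lpmatrix")
  mu <- exp(drop(Xp %*% coef(fld$fit)))
  g <- drop(crossprod(Xp, mu))
  sd_delta <- sqrt(drop(t(g) %*% vcov(fld$fit) %*% g))
  expect_lt(abs(est$sd - sd_delta) / sd_delta, 0.1)
})

test_that("SSB-indexed availability is constant within year and linear in SSB", {
  ssb <- tibble::tibble(year = 2010:2012, ssb = c(100, 250, 80))
  a <- sandeel_availability(ssb, c(2011, 2011))
  expect_equal(a$mean, c(250, 250))
  expect_equal(a$sd, c(0, 0))

  a2 <- sandeel_availability(dplyr::mutate(ssb, ssb = ssb * 2), 2011)
  expect_equal(a2$mean, 500)

  expect_error(sandeel_availability(ssb, 1999), "1999")

  acv <- sandeel_availability(ssb, 2010, cv = 0.2)
  expect_equal(acv$sd, 20)
})

test_that("rescaling maps the maximum to 100 and preserves ratios", {
  av <- tibble::tibble(species = c("a", "a", "a"), mean = c(5, 10, 20),
                       sd = c(1, 2, 4))
  r <- rescale_availability(av)
  expect_equal(r$mean, c(25, 50, 100))
  expect_equal(r$sd, c(5, 10, 20))
  expect_equal(rescale_availability(r), r)  # idempotent
  expect_equal(r$mean / r$mean[1], av$mean / av$mean[1])

  # global scaling preserves cross-species ratios
  av2 <- tibble::tibble(species = c("a", "b"), mean = c(10, 40),
                        sd = c(0, 0))
  g <- rescale_availability(av2, scale = "global")
  expect_equal(g$mean, c(25, 100))
  p <- rescale_availability(av2, scale = "per_species")
  expect_equal(p$mean, c(100, 100))

  expect_error(rescale_availability(
    tibble::tibble(species = "a", mean = 0, sd = 0)), "zero")
})
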