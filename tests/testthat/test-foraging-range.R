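# Regional filtering, track regularisation, MEC windows, the gamma range
# GLM and buffer prediction.

test_that("regional filter removes only the south-eastern exclusion zone", {
  tr <- tibble::tibble(lon = c(9.50, 9.50, 9.00),
                       lat = c(57.40, 57.20, 57.20))
  out <- filter_region(tr)
  expect_equal(nrow(out), 2)
  expect_true(all(out$lat == 57.40 | out$lon == 9.00))

  empty <- tr[0, ]
  expect_equal(nrow(filter_region(empty)), 0)

  set.seed(1)
  rnd <- tibble::tibble(lon = runif(1000, 7, 12), lat = runif(1000, 55, 59))
  expect_equal(filter_region(rnd),
               rnd[!(rnd$lat < 57.30 & rnd$lon > 9.37), ])
})

test_that("track regularisation interpolates on the chord", {
  tr <- tibble::tibble(
    animal_id = "A1",
    timestamp = as.POSIXct(c("2010-01-01 00:00", "2010-01-02 00:00"),
                           tz = "UTC"),
    lon = c(4.0, 4.5), lat = c(54.0, 54.3)
  )
  ctr <- c(4.25, 54.15)
  reg <- regularize_track(tr, step_hours = 6, center = ctr)
  expect_equal(nrow(reg), 5)  # 0, 6, 12, 18, 24 h
  # all interpolated points are collinear with the endpoints in
  # projected space (zero cross-track deviation)
  v <- c(reg$x[5] - reg$x[1], reg$y[5] - reg$y[1])
  w <- cbind(reg$x - reg$x[1], reg$y - reg$y[1])
  cross <- w[, 1] * v[2] - w[, 2] * v[1]
  expect_lt(max(abs(cross)), 1e-9)

  # an already-regular track is unchanged at its own timestamps
  reg2 <- regularize_track(reg, step_hours = 6, center = ctr)
  expect_equal(reg2$x, reg$x, tolerance = 1e-9)
  expect_equal(reg2$y, reg$y, tolerance = 1e-9)

  # long gaps split segments rather than being interpolated across
  tr_gap <- tibble::tibble(
    animal_id = "A1",
    timestamp = as.POSIXct("2010-01-01", tz = "UTC") +
      c(0, 6, 12, 100, 106, 112) * 3600,
    lon = c(4, 4.1, 4.2, 5, 5.1, 5.2), lat = rep(54, 6)
  )
  reg3 <- regularize_track(tr_gap, step_hours = 6, max_gap_hours = 24)
  expect_equal(sort(unique(reg3$segment)), c(1, 2))
})

test_that("minimum enclosing circle matches closed forms and brute force", {
  expect_equal(minimum_enclosing_circle(1, 2),
               list(center = c(1, 2), radius = 0))
  expect_error(minimum_enclosing_circle(numeric(0), numeric(0)), "empty")

  s <- 3.7
  tri <- cbind(c(0, s, s / 2), c(0, 0, s * sqrt(3) / 2))
  expect_equal(minimum_enclosing_circle(tri)$radius, s / sqrt(3),
               tolerance = 1e-12)

  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    x <- rnorm(n, sd = 40); y <- rnorm(n, sd = 40)
    got <- minimum_enclosing_circle(x, y)
    want <- mec_bruteforce(x, y)
    expect_equal(got$radius, want$radius, tolerance = 1e-9)
    # containment invariant
    expect_true(all(sqrt((x - got$center[1])^2 + (y - got$center[2])^2)
                    <= got$radius + 1e-6))
  }
})

test_that("MEC windows tile the track and match direct recomputation", {
  set.seed(4)
  n <- 33  # 8 days at 6-h steps, plus the initial position
  tr <- tibble::tibble(
    animal_id = "A1", age_class = "adult", sex = "F",
    timestamp = as.POSIXct("2010-03-01", tz = "UTC") + (0:(n - 1)) * 21600,
    lon = 4 + cumsum(rnorm(n, 0, 0.05)),
    lat = 54 + cumsum(rnorm(n, 0, 0.03))
  )
  reg <- regularize_track(tr)
  w <- build_mec_windows(reg, timeframe_days = 2)
  expect_equal(nrow(w), 4)
  expect_true(all(w$n_positions >= 2))
  expect_equal(as.character(unique(w$quarter)), "Q1")

  # each reported diameter equals the MEC of exactly the window's points
  for (i in seq_len(nrow(w))) {
    in_win <- reg$timestamp >= w$window_start[i] &
      reg$timestamp < w$window_start[i] + 2 * 86400
    direct <- minimum_enclosing_circle(reg$x[in_win], reg$y[in_win])
    expect_equal(w$diameter_km[i], 2 * direct$radius, tolerance = 1e-12)
    d <- sqrt((reg$x[in_win] - w$center_x[i])^2 +
                (reg$y[in_win] - w$center_y[i])^2)
    expect_true(all(d <= w$diameter_km[i] / 2 + 1e-6))
  }
})

test_that("range GLM reduces to the mean and recovers known coefficients", {
  set.seed(12)
  const <- tibble::tibble(
    diameter_km = rgamma(80, 4, 0.1),
    timeframe = factor(2, levels = c(2, 4, 6, 8)),
    age_class = "adult", sex = "F", quarter = "Q1"
  )
  m0 <- suppressWarnings(fit_range_glm(const, interactions = FALSE))
  expect_equal(unname(predict(m0$fit, type = "response")[1]),
               mean(const$diameter_km), tolerance = 1e-6)

  coefs <- default_range_coefs()
  w <- sim_range_windows(2000, coefs, seed = 13)
  fit <- fit_range_glm(w, interactions = FALSE)
  td <- tidy(fit)
  cmp <- td[match(names(coefs), td$term), ]
  expect_true(all(abs(cmp$estimate - coefs) <= 3 * cmp$std.error))
  # collinearity screen: balanced design, nothing near the threshold
  expect_true(all(fit$vif$vif < 4, na.rm = TRUE))
})

test_that("gamma IRLS agrees with an independent implementation", {
  w <- sim_range_windows(400, seed = 77)
  fit <- fit_range_glm(w, interactions = FALSE)
  X <- stats::model.matrix(~ timeframe + age_class + sex + quarter, w)
  beta <- irls_gamma_log(X, w$diameter_km)
  expect_equal(unname(coef(fit$fit)), unname(beta), tolerance = 1e-6)
})

test_that("stepwise AIC never selects a worse model than main effects", {
  w <- sim_range_windows(600, seed = 21)
  full <- fit_range_glm(w, interactions = TRUE)
  main <- fit_range_glm(w, interactions = FALSE)
  expect_lte(full$aic, main$aic + 1e-9)
})

test_that("buffers use the predicted diameter as radius", {
  w <- sim_range_windows(1000, seed = 5)
  model <- fit_range_glm(w, interactions = FALSE)

  strand <- tibble::tibble(
    stranding_id = c("s1", "s2"), lon = c(4, 4.2), lat = c(54, 54.1),
    date = as.Date(c("2012-02-01", "2012-02-01")),
    age_class = c("adult", "adult"), sex = c("F", "F")
  )
  for (tf in c(2, 4, 6, 8)) {
    buf <- predict_buffer(model, strand, tf)
    nd <- tibble::tibble(
      timeframe = factor(tf, levels = c(2, 4, 6, 8)),
      age_class = factor("adult", levels = model$levels$age_class),
      sex = factor("F", levels = model$levels$sex),
      quarter = factor("Q1", levels = model$levels$quarter)
    )
    expect_equal(buf$radius_km,
                 rep(unname(predict(model$fit, nd, type = "response")), 2))
  }
  # positive timeframe coefficients make the radius monotone in timeframe
  radii <- vapply(c(2, 4, 6, 8),
                  function(tf) predict_buffer(model, strand[1, ], tf)$radius_km,
                  0)
  expect_true(all(diff(radii) > 0))

  bad <- strand
  bad$age_class <- "calf"
  expect_error(predict_buffer(model, bad, 2), "unseen")
})

test_that("prediction grid covers every covariate combination", {
  w <- sim_range_windows(1000, seed = 6)
  model <- fit_range_glm(w, interactions = FALSE)
  tab <- predict_range_table(model)
  expect_equal(nrow(tab), 4 * 4 * 2 * 2)  # timeframe x quarter x age x sex
  expect_true(all(tab$diameter_km > 0))
  expect_true(all(c("timeframe", "age_class", "sex", "quarter",
                    "diameter_km", "se_km") %in% names(tab)))
})

test_that("range-GLM Wald intervals achieve nominal coverage", {
  # 95% intervals should cover the truth in >= 90% of replicates
  coefs <- default_range_coefs()
  hits <- 0L
  n_rep <- 60
  set.seed(30)
  for (r in seq_len(n_rep)) {
    w <- sim_range_windows(400, coefs)
    fit <- glm(diameter_km ~ timeframe + age_class + sex + quarter,
               family = Gamma(link = "log"), data = w)
    s <- summary(fit)$coefficients
    j <- "timeframe4"
    hits <- hits + (abs(s[j, 1] - coefs[[j]]) <= 1.96 * s[j, 2])
  }
  expect_gte(hits / n_rep, 0.9)
})
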