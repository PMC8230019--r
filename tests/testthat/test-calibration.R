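test_that("pairwise phase enumeration over the full event catalogue yields 171 phases", {
  obs <- full_event_chain()
  w <- constant_weather(15, start = "1998-01-01", n_days = 365)
  cat_ <- derive_phase_records(obs, w)
  expect_equal(nrow(cat_), choose(19, 2))
  expect_equal(nrow(cat_), 171L)
  expect_true(all(cat_$from_bbch < cat_$to_bbch))
  # E events -> E(E-1)/2 records, per group
  obs2 <- obs[1:5, ]
  expect_equal(nrow(derive_phase_records(obs2, w)), choose(5, 2))
  obs3 <- obs[1:2, ]
  expect_equal(nrow(derive_phase_records(obs3, w)), 1L)
})

test_that("phase records carry the observed length, its reciprocal and span means", {
  obs <- phenological_observations(
    site_id = "s1", latitude = 40, variety = "V", year = 1998L,
    bbch = c(1L, 61L), date = as.Date(c("1998-03-01", "1998-03-31")))
  w <- constant_weather(15, start = "1998-01-01", n_days = 365)
  rec <- derive_phase_records(obs, w)
  expect_equal(rec$S_obs, 30L)
  expect_equal(rec$DR_obs, 1 / 30)
  expect_equal(rec$T_mean, 15)
  # P_mean averages the daylength of the 30 days after the start
  days <- as.Date("1998-03-01") + 1:30
  expect_equal(rec$P_mean,
               mean(compute_daylength(40, as.integer(format(days, "%j")))))
})

test_that("reversed and weather-less phase pairs are rejected with a warning", {
  obs <- phenological_observations(
    site_id = "s1", latitude = 40, variety = "V", year = 1998L,
    bbch = c(1L, 61L), date = as.Date(c("1998-03-31", "1998-03-01")))
  w <- constant_weather(15, start = "1998-01-01", n_days = 365)
  expect_warning(rec <- derive_phase_records(obs, w), "rejected")
  expect_equal(nrow(rec), 0L)
  obs2 <- phenological_observations(
    site_id = "s9", latitude = 40, variety = "V", year = 1998L,
    bbch = c(1L, 61L), date = as.Date(c("1998-03-01", "1998-03-31")))
  expect_warning(rec2 <- derive_phase_records(obs2, w), "rejected")
  expect_equal(nrow(rec2), 0L)
})

test_that("phases observed at fewer than min_sites sites are discarded, boundary inclusive", {
  mk <- function(site, bbch_pair, lat = 40) {
    phenological_observations(site, lat, "V", 1998L, bbch_pair,
                              as.Date(c("1998-03-01", "1998-04-10")))
  }
  # phase 01->61 at 5 sites, phase 51->65 at 4 sites
  obs <- do.call(rbind, c(
    lapply(paste0("a", 1:5), mk, bbch_pair = c(1L, 61L)),
    lapply(paste0("b", 1:4), mk, bbch_pair = c(51L, 65L))))
  sites <- unique(obs$site_id)
  w <- do.call(rbind, lapply(sites, function(s)
    constant_weather(15, start = "1998-01-01", n_days = 365, site_id = s)))
  class(w) <- c("daily_weather", "data.frame")
  cat_ <- derive_phase_records(obs, w)
  kept <- filter_phases(cat_, min_sites = 5L)
  smry <- phase_summary(kept)
  expect_equal(nrow(smry), 1L)
  expect_equal(c(smry$from_bbch, smry$to_bbch), c(1L, 61L))
  expect_equal(smry$n_sites, 5L)  # exactly 5 sites is retained
  # empty catalogue passes through
  empty <- cat_[0, ]
  class(empty) <- class(cat_)
  expect_equal(nrow(filter_phases(empty)), 0L)
})

test_that("OLS recovers exact coefficients from noiseless linear rates", {
  temps <- seq(10, 24, length.out = 10)
  rec <- data.frame(DR_obs = -0.0180 + 0.0025 * temps, T_mean = temps)
  fit <- fit_dr(rec, "linear")
  expect_equal(fit$coefficients[1], -0.0180, tolerance = 1e-10)
  expect_equal(fit$coefficients[2], 0.0025, tolerance = 1e-10)
  expect_equal(fit$model$thresholds$t0, 7.2, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # polynomial and multiple kinds recover their generating surfaces too
  recp <- data.frame(DR_obs = -0.08 + 0.016 * temps - 4e-4 * temps^2,
                     T_mean = temps)
  fitp <- fit_dr(recp, "polynomial")
  expect_equal(fitp$coefficients, c(-0.08, 0.016, -4e-4), tolerance = 1e-8)
  set.seed(8)
  dl <- 10 + 5 * runif(10)  # not collinear with the temperature ladder
  recm <- data.frame(DR_obs = -0.05 + 0.003 * temps + 0.002 * dl,
                     T_mean = temps, P_mean = dl)
  fitm <- fit_dr(recm, "multiple")
  expect_equal(fitm$coefficients, c(-0.05, 0.003, 0.002), tolerance = 1e-8)
})

test_that("degenerate designs are fit errors and c >= 0 parabolas are flagged", {
  rec <- data.frame(DR_obs = runif(10, 0.01, 0.03), T_mean = rep(15, 10))
  expect_error(fit_dr(rec, "linear"), "zero variance")
  expect_error(fit_dr(data.frame(DR_obs = 0.02, T_mean = 15), "linear"),
               "at least 3 records")
  # upward-curving rates: fitted c > 0, unusable for simulation
  temps <- seq(5, 25, length.out = 12)
  recu <- data.frame(DR_obs = 0.001 * (temps - 15)^2 + 0.01,
                     T_mean = temps)
  fitu <- fit_dr(recu, "polynomial")
  expect_null(fitu$model)
  expect_match(fitu$warning, "downward")
})

test_that("fitted slope coverage is nominal under Gaussian rate noise", {
  set.seed(97)
  b_true <- 0.0025
  hits <- 0L
  est <- numeric(500)
  for (i in 1:500) {
    temps <- runif(70, 8, 22)
    rec <- data.frame(T_mean = temps,
                      DR_obs = -0.0180 + b_true * temps +
                        rnorm(70, 0, 0.002))
    f <- stats::lm(DR_obs ~ T_mean, data = rec)
    se <- summary(f)$coefficients["T_mean", "Std. Error"]
    est[i] <- coef(f)[["T_mean"]]
    if (abs(est[i] - b_true) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.93)
  # unbiased within Monte-Carlo error
  expect_lt(abs(mean(est) - b_true), 4 * sd(est) / sqrt(500))
})

test_that("r2 equals the squared Pearson correlation of fitted vs observed", {
  set.seed(5)
  temps <- runif(40, 8, 24)
  rec <- data.frame(T_mean = temps,
                    DR_obs = -0.018 + 0.0025 * temps + rnorm(40, 0, 0.003))
  fit <- fit_dr(rec, "linear")
  lmfit <- stats::lm(DR_obs ~ T_mean, data = rec)
  expect_equal(fit$r2, cor(fitted(lmfit), rec$DR_obs)^2)
})

test_that("bundled calibrations return the published coefficients", {
  m <- bundled_calibration(1, 61)
  expect_equal(c(m$a, m$b), c(-0.0180, 0.0025))
  expect_equal(m$thresholds$t0, 7.2)
  m2 <- bundled_calibration(7, 65)
  expect_equal(c(m2$a, m2$b), c(-0.0187, 0.0024))
  expect_equal(round(m2$thresholds$t0, 1), 7.8)
  expect_equal(attr(m2, "t0_printed"), 7.8)
  # the two phases where the published 1-decimal T0 and -a/b disagree:
  # both values are reported
  m3 <- bundled_calibration(1, 65)
  expect_equal(round(m3$thresholds$t0, 1), 6.6)
  expect_equal(attr(m3, "t0_printed"), 6.7)
  m4 <- bundled_calibration(51, 65)
  expect_equal(round(m4$thresholds$t0, 1), 10.8)
  expect_equal(attr(m4, "t0_printed"), 10.7)
  expect_error(bundled_calibration(11, 61), "supported phases")
  expect_equal(nrow(bundled_phases()), 6L)
})

test_that("per-plant dates reduce to the (lower) median date", {
  obs <- phenological_observations(
    site_id = "s1", latitude = 40, variety = "V", year = 1998L,
    bbch = rep(61L, 4),
    date = as.Date(c("1998-05-10", "1998-05-03", "1998-05-07",
                     "1998-05-21")))
  red <- reduce_plant_dates(obs)
  expect_equal(nrow(red), 1L)
  expect_equal(red$date, as.Date("1998-05-07"))  # lower median of 4
  obs3 <- obs[1:3, ]
  expect_equal(reduce_plant_dates(obs3)$date, as.Date("1998-05-07"))
})
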