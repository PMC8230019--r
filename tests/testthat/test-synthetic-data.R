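test_that("synthetic weather follows its sinusoid and is reproducible", {
  sp <- synthetic_site_spec("s1", 40, t_annual_mean = 15, amplitude = 0,
                            sigma_t = 0, years = 1998L)
  w <- generate_weather(sp, seed = 1L)
  expect_equal(nrow(w), 365L)
  expect_true(all(w$tmean_c == 15))
  sp2 <- synthetic_site_spec("s1", 40, 15, amplitude = 8, sigma_t = 1,
                             years = 1997:1999)
  wa <- generate_weather(sp2, seed = 4L)
  wb <- generate_weather(sp2, seed = 4L)
  expect_identical(wa, wb)
  expect_false(identical(wa, generate_weather(sp2, seed = 5L)))
  # three years of a zero-mean sinusoid plus noise average to Tm
  expect_equal(mean(wa$tmean_c), 15, tolerance = 0.2)
})

test_that("the default network spans the Italian olive latitudes", {
  specs <- synthetic_sites()
  lats <- vapply(specs, `[[`, numeric(1), "latitude")
  expect_length(specs, 7L)
  expect_equal(range(lats), c(37.41, 43.66))
  w <- generate_weather(specs, seed = 2L)
  expect_equal(length(unique(w$site_id)), 7L)
  # warmer in the south
  means <- tapply(w$tmean_c, w$site_id, mean)
  lat_of <- vapply(specs, `[[`, numeric(1), "latitude")
  names(lat_of) <- vapply(specs, `[[`, character(1), "site_id")
  expect_lt(cor(lat_of[names(means)], means), -0.9)
})

test_that("noise-free synthetic observations round-trip through the simulator", {
  sv0 <- survey_cache(sigma_obs = 0)
  # every observed phase length equals a fresh forward simulation
  cat_ <- suppressWarnings(derive_phase_records(sv0$observations,
                                                sv0$weather))
  rec <- cat_[cat_$from_bbch == 1 & cat_$to_bbch == 61, ]
  for (i in sample(nrow(rec), 10)) {
    r <- simulate_phase(rec$start_date[i], sv0$weather,
                        sv0$truth$phases$models[[1]],
                        site_id = rec$site_id[i])
    expect_equal(r$S, rec$S_obs[i])
  }
})

test_that("the noiseless pipeline recovers the generating coefficients within the whole-day bound", {
  # a ladder of constant-temperature sites spanning 15 degC, all above the
  # base temperature, isolates the only residual the noiseless pipeline
  # carries: phase lengths are whole days, so each observed rate 1/S is
  # deflated relative to the generating line by at most the final day's
  # rate (here < 5% at the warm end); exact coefficient recovery is
  # impossible at whole-day resolution
  true_m <- bundled_calibration(1, 61)
  specs <- lapply(1:12, function(i) {
    synthetic_site_spec(sprintf("L%02d", i), latitude = 40,
                        t_annual_mean = 10 + i * 1.25,
                        amplitude = 0, sigma_t = 0, years = 1998L)
  })
  w <- generate_weather(specs, seed = 3L)
  truth <- synthetic_truth(
    phases = {
      p <- data.frame(from_bbch = 1L, to_bbch = 61L)
      p$models <- list(true_m)
      p
    },
    sigma_obs = 0)
  gen <- generate_observations(truth, w, varieties = paste0("V", 1:5),
                               seed = 3L)
  rec <- derive_phase_records(gen$observations, w)
  rec <- rec[rec$from_bbch == 1L & rec$to_bbch == 61L, ]
  expect_gte(nrow(rec), 50L)
  expect_gte(diff(range(rec$T_mean)), 10)
  # every observed rate sits within one final-day rate below the true line
  true_rate <- dr_linear(rec$T_mean, true_m)
  expect_true(all(rec$DR_obs <= true_rate + 1e-12))
  # S = ceil(1/DR) implies 1/S > DR/(1+DR), i.e. deviation < DR^2
  expect_true(all(true_rate - rec$DR_obs < true_rate^2 + 1e-12))
  fit <- fit_dr(rec, "linear")
  expect_lt(abs(fit$coefficients[2] - true_m$b) / true_m$b, 0.05)
  expect_lt(abs(fit$coefficients[1] - true_m$a) / abs(true_m$a), 0.10)
  expect_lt(abs(fit$model$thresholds$t0 - true_m$thresholds$t0), 0.5)
})

test_that("observation jitter is applied per event and never collapses a phase", {
  sv <- survey_cache(sigma_obs = 3.5)
  cat_ <- suppressWarnings(derive_phase_records(sv$observations,
                                                sv$weather))
  expect_true(all(cat_$S_obs >= 1L))
  # jitter moves dates: observed dates differ from the true ones somewhere
  merged <- merge(sv$observations, sv$starts,
                  by = c("site_id", "variety", "year", "bbch"))
  expect_gt(mean(merged$date != merged$true_date), 0.5)
  jit <- as.numeric(merged$date - merged$true_date)
  expect_lt(abs(mean(jit)), 1)
  expect_lt(sd(jit), 6)
})

test_that("reverse modelling reconstructs noise-free budbreak dates", {
  sv0 <- survey_cache(sigma_obs = 0)
  model <- sv0$truth$phases$models[[1]]
  flowering <- sv0$starts[sv0$starts$bbch == 61L, ]
  budbreak <- sv0$starts[sv0$starts$bbch == 1L, ]
  key <- paste(flowering$site_id, flowering$variety, flowering$year)
  bb <- budbreak$true_date[match(key, paste(budbreak$site_id,
                                            budbreak$variety,
                                            budbreak$year))]
  n_exact <- 0L
  idx <- seq_len(nrow(flowering))
  for (i in idx) {
    s_rev <- reverse_budbreak(flowering$true_date[i], sv0$weather, model,
                              site_id = flowering$site_id[i])
    lateness <- as.numeric(s_rev - bb[i])
    expect_gte(lateness, 0)   # never earlier than the true start
    fwd <- simulate_phase(bb[i], sv0$weather, model,
                          site_id = flowering$site_id[i])
    overshoot <- fwd$trajectory$cum[fwd$S] - 1
    expected_lag <- sum(cumsum(fwd$trajectory$dr[seq_len(fwd$S)]) <=
                          overshoot)
    expect_equal(lateness, expected_lag)
    if (fwd$trajectory$dr[1] > overshoot) {
      expect_equal(lateness, 0)
      n_exact <- n_exact + 1L
    }
  }
  # exact recoveries occur whenever the first day's rate beats the
  # overshoot; under spring warming the first days carry the lowest rates,
  # so exactness is present but not dominant
  expect_gt(n_exact, 0L)
})
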