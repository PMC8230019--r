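#' Specification of one synthetic experimental site
#'
#' The generator emulates a Mediterranean multi-site survey: each site has
#' a latitude, a sinusoidal annual temperature cycle and i.i.d. daily
#' noise. The default network ([synthetic_sites()]) spans latitudes
#' 37.4-43.7 degrees N with annual means decreasing with latitude, the
#' range covered by Italian olive-growing sites.
#'
#' @param site_id Identifier.
#' @param latitude Decimal degrees.
#' @param t_annual_mean Annual mean temperature, degC.
#' @param amplitude Seasonal half-amplitude, degC (>= 0).
#' @param phase_shift Day-of-year offset of the sinusoid; the default 114
#'   puts the warmest day near the end of July.
#' @param sigma_t Standard deviation of daily temperature noise, degC.
#' @param years Integer vector of calendar years to generate.
#' @return A `site_spec` list.
#' @export
synthetic_site_spec <- function(site_id, latitude, t_annual_mean,
                                amplitude = 9, phase_shift = 114,
                                sigma_t = 1.5,
                                years = 1997:1999) {
  stopifnot(amplitude >= 0, sigma_t >= 0, length(years) >= 1L)
  structure(list(site_id = as.character(site_id),
                 latitude = as.numeric(latitude),
                 t_annual_mean = as.numeric(t_annual_mean),
                 amplitude = as.numeric(amplitude),
                 phase_shift = as.numeric(phase_shift),
                 sigma_t = as.numeric(sigma_t),
                 years = as.integer(years)),
            class = "site_spec")
}

#' Default synthetic site network
#'
#' Seven sites at the latitudes of the Italian olive-growing range
#' (37.4-43.7 degrees N), with annual mean temperature decreasing from
#' about 16.5 degC in the south to about 13.5 degC in the north.
#'
#' @param years Years to generate at every site.
#' @return A list of [synthetic_site_spec()] objects.
#' @export
synthetic_sites <- function(years = 1997:1999) {
  lats <- c(S1 = 43.66, S2 = 39.38, S3 = 41.03, S4 = 37.41,
            S5 = 37.60, S6 = 39.36, S7 = 42.99)
  lapply(names(lats), function(id) {
    synthetic_site_spec(id, lats[[id]],
                        t_annual_mean = 33 - 0.45 * lats[[id]],
                        years = years)
  })
}

#' Generate a synthetic daily weather series
#'
#' Daily mean temperature is a sinusoid of the day of year plus Gaussian
#' noise: `T(doy) = Tm + A sin(2 pi (doy - phase_shift) / 365) + eps`,
#' `eps ~ N(0, sigma_t)`. One value per calendar day of each requested
#' year. Values are clamped to the plausible range [-30, 50] degC.
#'
#' @param spec A [synthetic_site_spec()], or a list of them.
#' @param seed Integer seed; the same seed reproduces the same series.
#' @return A [daily_weather()] table.
#' @export
generate_weather <- function(spec, seed = 1L) {
  if (inherits(spec, "site_spec")) spec <- list(spec)
  set.seed(seed)
  per_site <- lapply(spec, function(sp) {
    dates <- do.call(c, lapply(sp$years, function(y) {
      seq(as.Date(sprintf("%d-01-01", y)),
          as.Date(sprintf("%d-12-31", y)), by = "day")
    }))
    doy <- date_doy(dates)
    temp <- sp$t_annual_mean +
      sp$amplitude * sin(2 * pi * (doy - sp$phase_shift) / 365) +
      stats::rnorm(length(dates), 0, sp$sigma_t)
    data.frame(site_id = sp$site_id, latitude = sp$latitude,
               date = dates, tmean_c = pmin(pmax(temp, -30), 50),
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, per_site)
  daily_weather(w$site_id, w$latitude, w$date, w$tmean_c)
}

#' Ground truth for synthetic phenology
#'
#' Bundles the generating DR models with the observation-noise settings.
#' Each phase is anchored at an already-generated event (the budbreak event
#' or an earlier phase's end), so phases must be listed in chain order.
#'
#' @param phases A data-frame-like list with columns `from_bbch`,
#'   `to_bbch`; element `models` is a list of [dr_model()] objects, one per
#'   row. Defaults to budbreak-to-flowering (01 -> 61) and
#'   budbreak-to-full-flowering (01 -> 65) under the bundled final
#'   calibrations.
#' @param start_bbch BBCH code of the chain's anchoring event (default 1,
#'   budbreak).
#' @param start_doy_range Budbreak day-of-year drawn uniformly in this
#'   range (default 30-120).
#' @param sigma_obs Standard deviation of the observation-date jitter in
#'   days (default 3.5, half the weekly survey interval); applied
#'   independently per event, rounded to whole days.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(phases = NULL, start_bbch = 1L,
                            start_doy_range = c(30L, 120L),
                            sigma_obs = 3.5) {
  if (is.null(phases)) {
    phases <- data.frame(from_bbch = c(1L, 1L), to_bbch = c(61L, 65L))
    phases$models <- list(bundled_calibration(1, 61),
                          bundled_calibration(1, 65))
  }
  stopifnot(sigma_obs >= 0,
            length(start_doy_range) == 2L,
            start_doy_range[1] <= start_doy_range[2])
  validate_bbch(c(start_bbch, phases$from_bbch, phases$to_bbch))
  structure(list(phases = phases, start_bbch = as.integer(start_bbch),
                 start_doy_range = as.integer(start_doy_range),
                 sigma_obs = sigma_obs),
            class = "synthetic_truth")
}

#' Generate synthetic phenological observations
#'
#' For each (site, variety, year) a budbreak date is drawn uniformly within
#' the truth's day-of-year range, each phase end is forward-simulated with
#' the true DR model by the summing-rates method, and every event date then
#' receives independent rounded Gaussian jitter emulating survey-date
#' uncertainty. Jitter that would make a phase non-positive is redrawn.
#' Records whose simulation does not complete within the horizon are
#' skipped with a warning.
#'
#' @param truth A [synthetic_truth()].
#' @param weather A [daily_weather()] table for the sites.
#' @param varieties Character vector of variety names given to every site
#'   (default 4 varieties).
#' @param seed Integer seed.
#' @param max_horizon Simulation horizon, days.
#' @return A list: `observations` (a `pheno_obs` data frame) and `starts`
#'   (data frame of the true, noise-free start dates per site, variety,
#'   year, with the true event dates of each phase end).
#' @export
generate_observations <- function(truth, weather,
                                  varieties = c("CAR", "COR", "PIC", "FRA"),
                                  seed = 1L, max_horizon = 366L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed + 1L)
  sites <- unique(weather$site_id)
  years <- sort(unique(as.integer(format(weather$date, "%Y"))))
  # last year is kept as simulation headroom only if a phase would run
  # past the series; observations are drawn in every year
  obs_rows <- list()
  start_rows <- list()
  n_skipped <- 0L
  for (site in sites) {
    lat <- site_latitude(weather, site)
    for (variety in varieties) {
      for (year in years) {
        doy0 <- sample(seq(truth$start_doy_range[1],
                           truth$start_doy_range[2]), 1L)
        start <- as.Date(sprintf("%d-01-01", year)) + (doy0 - 1L)
        event_dates <- stats::setNames(list(start),
                                       as.character(truth$start_bbch))
        ok <- TRUE
        for (p in seq_len(nrow(truth$phases))) {
          anchor <- event_dates[[as.character(truth$phases$from_bbch[p])]]
          if (is.null(anchor)) {
            stop("phase ", p, " anchored at an ungenerated event; ",
                 "order truth$phases as a chain", call. = FALSE)
          }
          res <- tryCatch(
            simulate_phase(anchor, weather, truth$phases$models[[p]],
                           site_id = site, max_horizon = max_horizon),
            error = function(e) NULL)
          if (is.null(res) || !res$completed) {
            ok <- FALSE
            break
          }
          event_dates[[as.character(truth$phases$to_bbch[p])]] <-
            res$end_date
        }
        if (!ok) {
          n_skipped <- n_skipped + 1L
          next
        }
        codes <- as.integer(names(event_dates))
        true_dates <- do.call(c, unname(event_dates))
        # per-event survey jitter; redraw while any phase collapses or an
        # event slips out of its calendar year (fall back to no jitter)
        jit <- rep(0L, length(codes))
        ord <- order(codes)
        for (attempt in 1:100) {
          cand <- round(stats::rnorm(length(codes), 0, truth$sigma_obs))
          jd <- true_dates + cand
          lengths_ok <- length(jd) == 1L ||
            all(diff(as.numeric(jd[ord])) >= 1)
          if (lengths_ok &&
              all(format(jd, "%Y") == as.character(year))) {
            jit <- cand
            break
          }
        }
        jd <- true_dates + jit
        obs_rows[[length(obs_rows) + 1L]] <- data.frame(
          site_id = site, latitude = lat, variety = variety,
          year = year, bbch = codes, date = jd,
          stringsAsFactors = FALSE)
        start_rows[[length(start_rows) + 1L]] <- data.frame(
          site_id = site, variety = variety, year = year,
          bbch = codes, true_date = true_dates,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " synthetic record(s) skipped: phase did not ",
            "complete within the horizon", call. = FALSE)
  }
  o <- do.call(rbind, obs_rows)
  obs <- phenological_observations(o$site_id, o$latitude, o$variety,
                                   o$year, o$bbch, o$date)
  list(observations = obs, starts = do.call(rbind, start_rows))
}

#' Generate a complete synthetic survey dataset
#'
#' Convenience wrapper: default seven-site network, default truth, one call.
#'
#' @param years Years to generate.
#' @param sigma_obs Observation jitter SD, days.
#' @param varieties Varieties per site.
#' @param seed Integer seed driving both weather and observations.
#' @return A list: `weather`, `observations`, `starts`, `truth`.
#' @export
generate_survey <- function(years = 1997:1999, sigma_obs = 3.5,
                            varieties = c("CAR", "COR", "PIC", "FRA"),
                            seed = 1L) {
  specs <- synthetic_sites(years = years)
  weather <- generate_weather(specs, seed = seed)
  truth <- synthetic_truth(sigma_obs = sigma_obs)
  gen <- generate_observations(truth, weather, varieties = varieties,
                               seed = seed)
  c(list(weather = weather, truth = truth), gen)
}
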