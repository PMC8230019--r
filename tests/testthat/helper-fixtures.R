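# Shared fixtures, generated in code.

# single-site weather with a constant temperature
constant_weather <- function(temp, start = as.Date("1998-01-01"),
                             n_days = 400L, site_id = "s1",
                             latitude = 40) {
  daily_weather(site_id, latitude,
                seq(as.Date(start), by = "day", length.out = n_days),
                rep(temp, n_days))
}

# one fully observed chain of all 19 BBCH events in a single
# (site, variety, year), events 5 days apart
full_event_chain <- function(start = as.Date("1998-02-01")) {
  codes <- bbch_catalogue()$code
  phenological_observations(
    site_id = "s1", latitude = 40, variety = "VAR", year = 1998L,
    bbch = codes, date = start + 5L * (seq_along(codes) - 1L))
}

# default synthetic survey, built once per test run
survey_cache <- local({
  cache <- list()
  function(sigma_obs = 3.5, seed = 7L) {
    key <- paste(sigma_obs, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- suppressWarnings(
        generate_survey(sigma_obs = sigma_obs, seed = seed))
    }
    cache[[key]]
  }
})

# independent brute-force summing-rates scan: day-by-day loop, no reuse of
# the package's vectorised path
brute_force_S <- function(dr_values) {
  total <- 0
  for (j in seq_along(dr_values)) {
    total <- total + dr_values[j]
    if (total >= 1) return(j)
  }
  NA_integer_
}
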