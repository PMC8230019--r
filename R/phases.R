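#' Assemble a table of phenological observations
#'
#' One row per dated BBCH event at a (site, variety, year). Codes are
#' checked against the olive catalogue ([bbch_catalogue()]) and each date
#' must fall in its stated year.
#'
#' @param site_id,variety Character identifiers.
#' @param latitude Decimal degrees.
#' @param year Calendar year of the observation.
#' @param bbch Integer BBCH event code.
#' @param date Event date (`Date` or ISO-8601 string).
#' @return A `pheno_obs` data frame.
#' @export
phenological_observations <- function(site_id, latitude, variety, year,
                                      bbch, date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable observation date", call. = FALSE)
  year <- as.integer(year)
  if (any(as.integer(format(date, "%Y")) != year)) {
    stop("observation date does not fall in its stated year",
         call. = FALSE)
  }
  if (any(latitude < -90 | latitude > 90)) {
    stop("latitude must be in [-90, 90]", call. = FALSE)
  }
  bbch <- validate_bbch(bbch)
  obs <- data.frame(site_id = as.character(site_id),
                    latitude = as.numeric(latitude),
                    variety = as.character(variety),
                    year = year, bbch = bbch, date = date,
                    stringsAsFactors = FALSE)
  class(obs) <- c("pheno_obs", "data.frame")
  obs
}

#' Reduce per-plant event dates to one date per site/variety/year/event
#'
#' Survey protocols record each event on several plants; the event date for
#' the group is the median of the per-plant dates. With an even number of
#' plants the lower median is taken, keeping the result an observed date
#' and the reduction deterministic.
#'
#' @param observations A `pheno_obs`-shaped data frame possibly holding
#'   several rows per (site, variety, year, bbch).
#' @return A `pheno_obs` data frame with one row per group.
#' @export
reduce_plant_dates <- function(observations) {
  key <- interaction(observations$site_id, observations$variety,
                     observations$year, observations$bbch, drop = TRUE)
  parts <- split(seq_len(nrow(observations)), key)
  rows <- vapply(parts, function(i) {
    d <- sort(observations$date[i])
    i[order(observations$date[i])][ceiling(length(d) / 2)]
  }, integer(1))
  out <- observations[sort(rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive phase records from observations and weather
#'
#' For every ordered pair of events (lower BBCH code first) observed within
#' the same (site, variety, year), builds one phase record: the observed
#' phase length `S_obs` in days, the developmental rate `DR_obs = 1/S_obs`,
#' and the mean air temperature `T_mean` and mean daylength `P_mean` over
#' the `S_obs` days following the start date (the same days that carry rate
#' in [simulate_phase()]). Pairs whose end does not fall after their start,
#' and pairs without adequate weather coverage, are dropped with a warning.
#'
#' @param observations A `pheno_obs` data frame (one date per site,
#'   variety, year, event; see [reduce_plant_dates()] for raw per-plant
#'   tables).
#' @param weather A [daily_weather()] table covering the phases' spans.
#' @return A `phase_catalogue` data frame, one row per phase record, with
#'   columns `from_bbch`, `to_bbch`, `site_id`, `variety`, `year`,
#'   `start_date`, `end_date`, `S_obs`, `DR_obs`, `T_mean`, `P_mean`.
#' @export
derive_phase_records <- function(observations, weather) {
  key <- interaction(observations$site_id, observations$variety,
                     observations$year, drop = TRUE)
  parts <- split(seq_len(nrow(observations)), key)
  recs <- vector("list", length(parts))
  n_rejected <- 0L
  for (g in seq_along(parts)) {
    idx <- parts[[g]]
    o <- observations[idx, , drop = FALSE]
    o <- o[order(o$bbch), , drop = FALSE]
    if (anyDuplicated(o$bbch)) {
      stop("several dates for one event within a (site, variety, year); ",
           "reduce with reduce_plant_dates() first", call. = FALSE)
    }
    n <- nrow(o)
    if (n < 2L) next
    pairs <- utils::combn(n, 2L)
    out <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      S <- as.integer(o$date[j] - o$date[i])
      if (S < 1L) {
        n_rejected <- n_rejected + 1L
        next
      }
      days <- seq(o$date[i] + 1L, by = "day", length.out = S)
      temps <- tryCatch(weather_window(weather, o$site_id[i], days),
                        error = function(e) NULL)
      if (is.null(temps)) {
        n_rejected <- n_rejected + 1L
        next
      }
      out[[p]] <- data.frame(
        from_bbch = o$bbch[i], to_bbch = o$bbch[j],
        site_id = o$site_id[i], variety = o$variety[i], year = o$year[i],
        start_date = o$date[i], end_date = o$date[j],
        S_obs = S, DR_obs = 1 / S,
        T_mean = mean(temps),
        P_mean = mean(compute_daylength(o$latitude[i], date_doy(days))),
        stringsAsFactors = FALSE)
    }
    recs[[g]] <- do.call(rbind, out)
  }
  if (n_rejected > 0L) {
    warning(n_rejected, " phase record(s) rejected (non-positive length ",
            "or missing weather)", call. = FALSE)
  }
  cat_df <- do.call(rbind, recs)
  if (is.null(cat_df)) {
    cat_df <- data.frame(from_bbch = integer(), to_bbch = integer(),
                         site_id = character(), variety = character(),
                         year = integer(), start_date = as.Date(character()),
                         end_date = as.Date(character()), S_obs = integer(),
                         DR_obs = numeric(), T_mean = numeric(),
                         P_mean = numeric(), stringsAsFactors = FALSE)
  }
  rownames(cat_df) <- NULL
  class(cat_df) <- c("phase_catalogue", "data.frame")
  cat_df
}

#' Per-phase summary of a catalogue
#'
#' @param catalogue A [derive_phase_records()] catalogue.
#' @return A data frame with one row per (from_bbch, to_bbch): `n_sites`
#'   (distinct sites), `n_records`, `S_mean` and `S_sd` (mean and standard
#'   deviation of the observed phase lengths, days).
#' @export
phase_summary <- function(catalogue) {
  if (nrow(catalogue) == 0L) {
    return(data.frame(from_bbch = integer(), to_bbch = integer(),
                      n_sites = integer(), n_records = integer(),
                      S_mean = numeric(), S_sd = numeric()))
  }
  key <- interaction(catalogue$from_bbch, catalogue$to_bbch, drop = TRUE)
  parts <- split(seq_len(nrow(catalogue)), key)
  out <- lapply(parts, function(i) {
    data.frame(from_bbch = catalogue$from_bbch[i][1L],
               to_bbch = catalogue$to_bbch[i][1L],
               n_sites = length(unique(catalogue$site_id[i])),
               n_records = length(i),
               S_mean = mean(catalogue$S_obs[i]),
               S_sd = stats::sd(catalogue$S_obs[i]))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$from_bbch, out$to_bbch), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard phases observed at too few sites
#'
#' Phases whose records come from fewer than `min_sites` distinct
#' experimental sites are dropped, guaranteeing spatial heterogeneity in
#' every calibration sample.
#'
#' @param catalogue A [derive_phase_records()] catalogue.
#' @param min_sites Minimum number of distinct sites (default 5, boundary
#'   inclusive).
#' @return The filtered `phase_catalogue`.
#' @export
filter_phases <- function(catalogue, min_sites = 5L) {
  if (nrow(catalogue) == 0L) return(catalogue)
  smry <- phase_summary(catalogue)
  keep <- smry[smry$n_sites >= min_sites, c("from_bbch", "to_bbch")]
  sel <- paste(catalogue$from_bbch, catalogue$to_bbch) %in%
    paste(keep$from_bbch, keep$to_bbch)
  out <- catalogue[sel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phase_catalogue", "data.frame")
  out
}
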