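#' Simulate a phenological phase by the summing-rates method
#'
#' Starting from the date of the opening event, daily developmental rates
#' are computed from the site's weather (and daylength, for the multiple
#' model) and accumulated. The phase completes on the first day on which the
#' running sum reaches 1; the predicted phase length S is the number of days
#' accumulated, so the end date is `start_date + S`. Day counting follows
#' the convention that the start day itself contributes no rate: day j = 1
#' is the first day after the start event, which makes simulated lengths
#' directly comparable with observed lengths `DOY_end - DOY_start`.
#'
#' @param start_date Date of the phase's opening event (`Date` or ISO
#'   string).
#' @param weather A [daily_weather()] table covering the horizon for the
#'   record's site.
#' @param model A [dr_model()].
#' @param site_id Site whose series to use; may be omitted when the weather
#'   table holds a single site.
#' @param max_horizon Maximum number of days to accumulate (default 366).
#' @return A `simulation_result` list: `S` (predicted length, days;
#'   `NA` if not completed), `end_date`, `completed`, and `trajectory`
#'   (a data frame of date, daily rate `dr`, and running sum `cum`).
#' @examples
#' w <- daily_weather("s1", 40, seq(as.Date("1998-03-01"), by = "day",
#'                                  length.out = 120), rep(17, 120))
#' m <- dr_model("linear", -0.0180, 0.0025)
#' simulate_phase("1998-03-01", w, m)$S  # 41 days at a constant 17 degC
#' @export
simulate_phase <- function(start_date, weather, model, site_id = NULL,
                           max_horizon = 366L) {
  start_date <- as.Date(start_date)
  stopifnot(inherits(model, "dr_model"), max_horizon >= 1L)
  if (is.null(site_id)) {
    site_id <- unique(weather$site_id)
    if (length(site_id) != 1L) {
      stop("weather table holds several sites; pass site_id",
           call. = FALSE)
    }
  }
  days <- seq(start_date + 1L, by = "day", length.out = max_horizon)
  # clip the horizon to the available series: completion past the end of the
  # record is indistinguishable from non-completion within it
  avail <- weather$date[weather$site_id == site_id]
  if (length(avail) == 0L) {
    stop("no weather for site '", site_id, "'", call. = FALSE)
  }
  if (days[1] > max(avail)) {
    stop("weather for site '", site_id, "' ends before the start date",
         call. = FALSE)
  }
  days <- days[days <= max(avail)]
  temps <- weather_window(weather, site_id, days)
  dl <- if (model$kind == "multiple") {
    compute_daylength(site_latitude(weather, site_id), date_doy(days))
  } else NULL
  dr <- dr_rate(model, temps, dl)
  cum <- cumsum(dr)
  hit <- which(cum >= 1)
  completed <- length(hit) > 0L
  S <- if (completed) hit[1L] else NA_integer_
  structure(list(
    S = S,
    end_date = if (completed) start_date + S else as.Date(NA),
    completed = completed,
    start_date = start_date,
    trajectory = data.frame(date = days, dr = dr, cum = cum)
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  if (x$completed) {
    cat("<simulation_result> completed: S =", x$S, "days, end date",
        format(x$end_date), "\n")
  } else {
    cat("<simulation_result> not completed within",
        nrow(x$trajectory), "days (cumulative rate",
        round(max(x$trajectory$cum), 3), ")\n")
  }
  invisible(x)
}

#' Reconstruct a budbreak (phase start) date from an observed end date
#'
#' Reverse application of the summing-rates method: walking backwards from
#' the observed end of the phase (typically a flowering date), daily rates
#' are accumulated until they reach 1. The returned start estimate is the
#' latest date `s` such that the rates summed over `(s, end_date]` reach 1,
#' so forward simulation from `s` completes no later than `end_date`.
#'
#' Because phase completion is resolved at whole days, the forward
#' accumulation generally overshoots 1 slightly; when the leading days of
#' the true phase contribute less rate than that overshoot, the
#' reconstructed start falls later than the true start by exactly the
#' number of leading days whose cumulative rate fits inside the overshoot
#' (zero whenever the first day's rate alone exceeds it). It is never
#' earlier than the true start.
#'
#' @param end_date Observed date of the phase's closing event.
#' @param weather A [daily_weather()] table covering the lookback window.
#' @param model A [dr_model()].
#' @param site_id Site whose series to use; may be omitted for a single-site
#'   table.
#' @param max_lookback Maximum days to look back (default 366).
#' @return The estimated start `Date`.
#' @export
reverse_budbreak <- function(end_date, weather, model, site_id = NULL,
                             max_lookback = 366L) {
  end_date <- as.Date(end_date)
  stopifnot(inherits(model, "dr_model"), max_lookback >= 1L)
  if (is.null(site_id)) {
    site_id <- unique(weather$site_id)
    if (length(site_id) != 1L) {
      stop("weather table holds several sites; pass site_id",
           call. = FALSE)
    }
  }
  days <- seq(end_date - max_lookback + 1L, end_date, by = "day")
  avail <- weather$date[weather$site_id == site_id]
  if (length(avail) == 0L) {
    stop("no weather for site '", site_id, "'", call. = FALSE)
  }
  days <- days[days >= min(avail)]
  if (length(days) == 0L || max(avail) < end_date) {
    stop("weather for site '", site_id, "' does not cover the lookback ",
         "window ending ", format(end_date), call. = FALSE)
  }
  temps <- weather_window(weather, site_id, days)
  dl <- if (model$kind == "multiple") {
    compute_daylength(site_latitude(weather, site_id), date_doy(days))
  } else NULL
  dr <- dr_rate(model, temps, dl)
  # cumulative sum of the last k days' rates, k = 1 .. length(days)
  tail_sum <- cumsum(rev(dr))
  hit <- which(tail_sum >= 1)
  if (length(hit) == 0L) {
    stop("developmental rates over the ", length(days),
         "-day lookback sum to ", round(tail_sum[length(tail_sum)], 3),
         " < 1: no start date can explain the end date", call. = FALSE)
  }
  end_date - hit[1L]
}
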