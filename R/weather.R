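#' Assemble a daily weather table
#'
#' Validates and normalises a per-site daily mean temperature series. One
#' table may hold several sites; each site carries one latitude and an
#' ordered, duplicate-free daily series. Temperatures outside [-30, 50]
#' degrees C are rejected as implausible for the target domain. Gaps in a
#' series are allowed at load time; they are interpolated (up to 3
#' consecutive missing days) or rejected at simulation time.
#'
#' @param site_id Character vector of site identifiers.
#' @param latitude Numeric latitude per row, decimal degrees.
#' @param date `Date` vector (or ISO-8601 strings).
#' @param tmean_c Daily mean air temperature, degrees C.
#' @return A `daily_weather` data frame with columns `site_id`, `latitude`,
#'   `date`, `tmean_c`, sorted by site and date.
#' @export
daily_weather <- function(site_id, latitude, date, tmean_c) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable date in weather input", call. = FALSE)
  if (any(latitude < -90 | latitude > 90)) {
    stop("latitude must be in [-90, 90]", call. = FALSE)
  }
  if (any(!is.finite(tmean_c)) ||
      any(tmean_c < -30 | tmean_c > 50)) {
    stop("temperatures must be finite and within [-30, 50] degC",
         call. = FALSE)
  }
  w <- data.frame(site_id = as.character(site_id),
                  latitude = as.numeric(latitude),
                  date = date, tmean_c = as.numeric(tmean_c),
                  stringsAsFactors = FALSE)
  w <- w[order(w$site_id, w$date), , drop = FALSE]
  dup <- duplicated(w[, c("site_id", "date")])
  if (any(dup)) {
    stop("duplicate (site, date) in weather: ",
         paste(unique(paste(w$site_id[dup], w$date[dup])), collapse = "; "),
         call. = FALSE)
  }
  lat_per_site <- tapply(w$latitude, w$site_id,
                         function(x) length(unique(x)))
  if (any(lat_per_site > 1L)) {
    stop("a site must have a single latitude", call. = FALSE)
  }
  rownames(w) <- NULL
  class(w) <- c("daily_weather", "data.frame")
  w
}

#' Latitude of one site in a weather table
#' @keywords internal
site_latitude <- function(weather, site_id) {
  lat <- weather$latitude[weather$site_id == site_id][1L]
  if (is.na(lat)) {
    stop("site '", site_id, "' not found in weather table", call. = FALSE)
  }
  lat
}

#' Extract a contiguous daily temperature window for one site
#'
#' Returns the temperatures for each requested calendar day. Gaps of at most
#' `max_gap` consecutive missing days are filled by linear interpolation
#' between the neighbouring observed days; longer gaps, or requested days
#' outside the observed span, are a hard error.
#'
#' @param weather A [daily_weather()] table.
#' @param site_id Site to extract.
#' @param dates `Date` vector of consecutive days wanted.
#' @param max_gap Longest interpolatable run of missing days (default 3).
#' @return Numeric vector of temperatures, one per requested day.
#' @keywords internal
weather_window <- function(weather, site_id, dates, max_gap = 3L) {
  s <- weather[weather$site_id == site_id, , drop = FALSE]
  if (nrow(s) == 0L) {
    stop("no weather for site '", site_id, "'", call. = FALSE)
  }
  if (min(dates) < min(s$date) || max(dates) > max(s$date)) {
    stop("weather for site '", site_id, "' does not cover ",
         format(min(dates)), "..", format(max(dates)), call. = FALSE)
  }
  idx <- match(dates, s$date)
  if (!anyNA(idx)) return(s$tmean_c[idx])
  # interior gaps: bound their run lengths over the full observed span
  full <- seq(min(s$date), max(s$date), by = "day")
  present <- full %in% s$date
  r <- rle(present)
  gap_end <- cumsum(r$lengths)
  gap_start <- gap_end - r$lengths + 1L
  for (k in which(!r$values & r$lengths > max_gap)) {
    gap_days <- full[gap_start[k]:gap_end[k]]
    if (any(dates %in% gap_days)) {
      stop("weather gap of ", r$lengths[k], " days (",
           format(gap_days[1]), "..", format(gap_days[length(gap_days)]),
           ") at site '", site_id, "' exceeds the ", max_gap,
           "-day interpolation tolerance", call. = FALSE)
    }
  }
  stats::approx(as.numeric(s$date), s$tmean_c, xout = as.numeric(dates),
                method = "linear", rule = 1)$y
}
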