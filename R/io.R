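#' Read a daily weather CSV
#'
#' Expects a header `site_id, latitude, date, tmean_c` with ISO-8601 dates.
#' Parsing problems are reported with the offending file line number
#' (header = line 1). Duplicate (site, date) rows are an error.
#'
#' @param path Path to the CSV file.
#' @return A [daily_weather()] table.
#' @export
read_weather <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  need <- c("site_id", "latitude", "date", "tmean_c")
  if (!all(need %in% names(raw))) {
    stop("weather file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  line_no <- seq_len(nrow(raw)) + 1L
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(date))
  if (length(bad) > 0L) {
    stop("unparseable date at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x))
    if (length(bad) > 0L) {
      stop("unparseable ", col, " at line ", bad[1L] + 1L, " of ", path,
           call. = FALSE)
    }
    x
  }
  dup <- which(duplicated(paste(raw$site_id, raw$date)))
  if (length(dup) > 0L) {
    stop("duplicate (site, date) at line ", line_no[dup[1L]], " of ", path,
         call. = FALSE)
  }
  daily_weather(raw$site_id, num("latitude"), date, num("tmean_c"))
}

#' Read a phenological observation CSV
#'
#' Expects a header `site_id, latitude, variety, year, bbch, date`. BBCH
#' codes must belong to the olive catalogue and each date must fall in its
#' stated year.
#'
#' @param path Path to the CSV file.
#' @return A `pheno_obs` data frame ([phenological_observations()]);
#'   zero-row input yields an empty table.
#' @export
read_observations <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  need <- c("site_id", "latitude", "variety", "year", "bbch", "date")
  if (!all(need %in% names(raw))) {
    stop("observation file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(phenological_observations(character(), numeric(), character(),
                                     integer(), integer(),
                                     as.Date(character())))
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(date))
  if (length(bad) > 0L) {
    stop("unparseable date at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  phenological_observations(raw$site_id, as.numeric(raw$latitude),
                            raw$variety, as.integer(raw$year),
                            as.integer(raw$bbch), date)
}

#' Write weather / observation tables as CSV
#'
#' Inverse of [read_weather()] and [read_observations()]; round trips are
#' lossless at the printed precision.
#'
#' @param x The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(x, path) {
  out <- data.frame(site_id = x$site_id, latitude = x$latitude,
                    date = format(x$date, "%Y-%m-%d"),
                    tmean_c = x$tmean_c)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @export
write_observations <- function(x, path) {
  out <- data.frame(site_id = x$site_id, latitude = x$latitude,
                    variety = x$variety, year = x$year, bbch = x$bbch,
                    date = format(x$date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise calibration results to JSON
#'
#' One JSON object per calibration with keys `phase`, `kind`, `a`, `b`,
#' `c`, `thresholds`, `r2`, `p_value`, `n_sites`, `n_records`.
#'
#' @param results A `calibration_result` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibrations <- function(results, path) {
  if (inherits(results, "calibration_result")) results <- list(results)
  objs <- lapply(results, function(r) {
    cf <- r$coefficients
    list(phase = if (is.null(r$phase)) NULL else unname(r$phase),
         kind = r$kind,
         a = cf[1L], b = cf[2L],
         c = if (length(cf) > 2L) cf[3L] else NULL,
         thresholds = if (is.null(r$model)) NULL else r$model$thresholds,
         r2 = r$r2, p_value = r$p_value,
         n_sites = r$n_sites, n_records = r$n_records)
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read calibrations written by [write_calibrations()]
#'
#' @param path Path to the JSON file.
#' @return A list of [dr_model()] objects with attributes `phase`, `r2`,
#'   `p_value`, `n_sites`, `n_records`.
#' @export
read_calibrations <- function(path) {
  objs <- jsonlite::read_json(path)
  lapply(objs, function(o) {
    m <- switch(o$kind,
      linear = dr_model("linear", o$a, o$b),
      multiple = {
        # the stored thresholds are sufficient for simulation, so the
        # training-sample reference values need not round-trip
        th <- o$thresholds
        structure(list(kind = "multiple", a = o$a, b = o$b, c = o$c,
                       t_ref = NULL, p_ref = NULL,
                       thresholds = list(t0m = th$t0m, p0m = th$p0m)),
                  class = "dr_model")
      },
      polynomial = dr_model("polynomial", o$a, o$b, o$c),
      stop("unknown model kind '", o$kind, "' in ", path, call. = FALSE))
    if (!is.null(o$phase)) {
      attr(m, "phase") <- c(from = o$phase[[1L]], to = o$phase[[2L]])
    }
    attr(m, "r2") <- o$r2
    attr(m, "p_value") <- o$p_value
    attr(m, "n_sites") <- o$n_sites
    attr(m, "n_records") <- o$n_records
    m
  })
}

#' Serialise cross-validation reports to JSON
#'
#' One object per phase x model kind with the ensemble statistics, sample
#' description and CV settings.
#'
#' @param reports A `cv_report` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_reports <- function(reports, path) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  objs <- lapply(reports, function(r) {
    list(phase = if (is.null(r$phase)) NULL else unname(r$phase),
         kind = r$kind,
         r2 = r$r2,
         adj_r2 = if (r$kind == "multiple") r$adj_r2 else NULL,
         rmse = r$rmse, mbe = r$mbe,
         K = r$K, N = r$N, seed = r$seed,
         n_sites = r$n_sites, n_records = r$n_records,
         n_fold_runs = r$n_fold_runs)
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
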