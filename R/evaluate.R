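#' Agreement metrics between simulated and observed phase lengths
#'
#' RMSE is the root of the mean squared difference, MBE the mean signed
#' difference (simulated minus observed), both in days. r2 is the squared
#' Pearson correlation between simulated and observed values; with
#' zero-variance observations it is undefined and reported as `NA`.
#'
#' @param simulated,observed Numeric vectors of equal length (>= 2), days.
#' @return A named list `r2`, `rmse`, `mbe`.
#' @examples
#' compute_metrics(c(10, 20), c(12, 18))  # rmse 2, mbe 0
#' @export
compute_metrics <- function(simulated, observed) {
  if (length(simulated) != length(observed)) {
    stop("simulated and observed must have equal length", call. = FALSE)
  }
  if (length(observed) < 2L) {
    stop("need at least 2 paired values", call. = FALSE)
  }
  err <- simulated - observed
  r2 <- if (stats::var(observed) == 0 || stats::var(simulated) == 0) {
    NA_real_
  } else {
    stats::cor(simulated, observed)^2
  }
  list(r2 = r2,
       rmse = sqrt(mean(err^2)),
       mbe = mean(err))
}

#' Repeated K-fold cross-validation of a DR model for one phase
#'
#' The phase's records are shuffled and split into K folds of near-equal
#' size (differing by at most one). Each fold in turn is held out: a DR
#' function of the requested kind is fitted by OLS on the remaining folds
#' ([fit_dr()]), and each held-out record's phase length is simulated by
#' the summing-rates method ([simulate_phase()]) from its own observed
#' start date and its site's daily weather. r2, RMSE and MBE are computed
#' per fold-run and the whole split-shuffle cycle is repeated N times; the
#' report is the ensemble mean over all K x N fold-runs. For the multiple
#' kind the per-fold r2 is additionally reported as adjusted r2.
#'
#' Held-out records whose simulation does not complete within the horizon
#' are dropped from that fold's metrics; folds left with fewer than two
#' validated records, or with too few training records to fit, are skipped
#' with a warning.
#'
#' @param records Phase records of a single (from, to) phase.
#' @param weather A [daily_weather()] table covering every record's span.
#' @param kind Model kind passed to [fit_dr()].
#' @param K Number of folds (default 5).
#' @param N Number of shuffle repeats (default 10).
#' @param seed Integer seed; repeat i derives its own stream from it.
#' @param max_horizon Simulation horizon in days.
#' @return A `cv_report` list: `phase`, `kind`, `r2`, `adj_r2`, `rmse`,
#'   `mbe` (ensemble means), `K`, `N`, `seed`, `n_sites`, `n_records`,
#'   `n_fold_runs`, `n_skipped`, and `fold_metrics` (per-fold-run data
#'   frame).
#' @export
kfold_cross_validate <- function(records, weather,
                                 kind = c("linear", "multiple",
                                          "polynomial"),
                                 K = 5L, N = 10L, seed = 1L,
                                 max_horizon = 366L) {
  kind <- match.arg(kind)
  n <- nrow(records)
  if (n < K) stop("need at least K = ", K, " records", call. = FALSE)
  k_coef <- switch(kind, linear = 2L, multiple = 3L, polynomial = 3L)
  fold_rows <- vector("list", K * N)
  n_skipped <- 0L
  row_i <- 0L
  for (rep_i in seq_len(N)) {
    # derived per-repeat seed keeps repeats independent yet reproducible
    set.seed(seed * 1000L + rep_i)
    perm <- sample.int(n)
    fold_of <- rep_len(seq_len(K), n)[order(perm)]
    for (k in seq_len(K)) {
      row_i <- row_i + 1L
      val_idx <- which(fold_of == k)
      train <- records[-val_idx, , drop = FALSE]
      if (nrow(train) < k_coef + 1L) {
        n_skipped <- n_skipped + 1L
        next
      }
      cal <- tryCatch(fit_dr(train, kind), error = function(e) NULL)
      if (is.null(cal) || is.null(cal$model)) {
        n_skipped <- n_skipped + 1L
        next
      }
      sim <- rep(NA_real_, length(val_idx))
      for (v in seq_along(val_idx)) {
        rec <- records[val_idx[v], , drop = FALSE]
        res <- tryCatch(
          simulate_phase(rec$start_date, weather, cal$model,
                         site_id = rec$site_id,
                         max_horizon = max_horizon),
          error = function(e) NULL)
        if (!is.null(res) && res$completed) sim[v] <- res$S
      }
      ok <- !is.na(sim)
      if (sum(ok) < 2L) {
        n_skipped <- n_skipped + 1L
        next
      }
      m <- compute_metrics(sim[ok], records$S_obs[val_idx][ok])
      n_val <- sum(ok)
      fold_rows[[row_i]] <- data.frame(
        repeat_i = rep_i, fold = k, n_val = n_val,
        r2 = m$r2,
        adj_r2 = if (!is.na(m$r2) && n_val > k_coef) {
          1 - (1 - m$r2) * (n_val - 1) / (n_val - k_coef)
        } else NA_real_,
        rmse = m$rmse, mbe = m$mbe)
    }
  }
  fm <- do.call(rbind, fold_rows)
  if (is.null(fm) || nrow(fm) == 0L) {
    stop("all ", K * N, " fold-runs were skipped: cross-validation ",
         "impossible for this phase", call. = FALSE)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " of ", K * N, " fold-runs skipped", call. = FALSE)
  }
  phase <- if (all(c("from_bbch", "to_bbch") %in% names(records))) {
    c(from = records$from_bbch[1L], to = records$to_bbch[1L])
  } else NULL
  structure(list(
    phase = phase, kind = kind,
    r2 = mean(fm$r2, na.rm = TRUE),
    adj_r2 = mean(fm$adj_r2, na.rm = TRUE),
    rmse = mean(fm$rmse),
    mbe = mean(fm$mbe),
    K = K, N = N, seed = seed,
    n_sites = if ("site_id" %in% names(records))
      length(unique(records$site_id)) else NA_integer_,
    n_records = n,
    n_fold_runs = nrow(fm), n_skipped = n_skipped,
    fold_metrics = fm
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>")
  if (!is.null(x$phase)) {
    cat(sprintf(" phase %02d -> %02d", x$phase[["from"]], x$phase[["to"]]))
  }
  cat("\n  kind:", x$kind, sprintf(" (K = %d, N = %d)", x$K, x$N),
      "\n  ensemble r2 =", round(x$r2, 3),
      if (x$kind == "multiple") paste0("(adjusted ", round(x$adj_r2, 3), ")")
      else "",
      " RMSE =", round(x$rmse, 2), "d",
      " MBE =", round(x$mbe, 2), "d",
      "\n  n =", x$n_records, "records /", x$n_sites, "sites;",
      x$n_fold_runs, "fold-runs\n")
  invisible(x)
}

#' Select cross-validated phases
#'
#' Keeps the reports whose ensemble r2 exceeds `r2_min` and whose ensemble
#' RMSE is below `rmse_max` (both strict). The default RMSE gate of 7 days
#' reflects the measurement uncertainty of weekly field surveys.
#'
#' @param reports A list of `cv_report` objects.
#' @param r2_min Minimum ensemble r2 (exclusive; default 0.8).
#' @param rmse_max Maximum ensemble RMSE in days (exclusive; default 7).
#' @return The selected sub-list, in the original order.
#' @export
select_cross_validated <- function(reports, r2_min = 0.8, rmse_max = 7) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  keep <- vapply(reports, function(r) {
    !is.na(r$r2) && r$r2 > r2_min && r$rmse < rmse_max
  }, logical(1))
  reports[keep]
}
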