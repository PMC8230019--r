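#' Construct a developmental-rate (DR) model
#'
#' A DR model maps daily mean air temperature (and, for the multiple kind,
#' daylength) to a daily developmental rate in d^-1. Three response shapes
#' are supported:
#' \describe{
#'   \item{linear}{`DR = a + b*T`, active above the base temperature
#'     `T0 = -a/b`.}
#'   \item{multiple}{`DR = a + b*T + c*P` with daylength `P` in hours,
#'     active when `T > T0m` and `P > P0m`.}
#'   \item{polynomial}{`DR = a + b*T + c*T^2`, a downward parabola active
#'     between its two roots `Tp1 < Tp2`.}
#' }
#' Below (or, for the polynomial, outside) the critical thresholds the daily
#' rate is clipped to zero: development is assumed nil.
#'
#' @param kind One of `"linear"`, `"multiple"`, `"polynomial"`.
#' @param a Intercept, d^-1.
#' @param b Temperature coefficient, per degree C per day.
#' @param c Second coefficient: daylength coefficient (per hour per day) for
#'   the multiple kind, quadratic temperature coefficient (per degree C
#'   squared per day) for the polynomial kind. Ignored for the linear kind.
#' @param t_ref,p_ref Reference (training-sample mean) temperature and
#'   daylength, required for the multiple kind: its critical values are the
#'   x-intercepts of the fitted plane projected onto each predictor axis,
#'   holding the other predictor at its reference value.
#' @return An object of class `dr_model` with the coefficients and the
#'   derived critical thresholds (see [critical_thresholds()]).
#' @examples
#' m <- dr_model("linear", a = -0.0180, b = 0.0025)
#' m$thresholds$t0  # base temperature 7.2 degC
#' @export
dr_model <- function(kind = c("linear", "multiple", "polynomial"),
                     a, b, c = NULL, t_ref = NULL, p_ref = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (kind == "linear") {
    c <- NULL
  } else {
    if (is.null(c) || !is.finite(c)) {
      stop("model kind '", kind, "' requires a finite coefficient c",
           call. = FALSE)
    }
    c <- as.numeric(c)
  }
  m <- structure(
    list(kind = kind, a = as.numeric(a), b = as.numeric(b), c = c,
         t_ref = t_ref, p_ref = p_ref, thresholds = NULL),
    class = "dr_model")
  m$thresholds <- critical_thresholds(m)
  m
}

#' Derive the critical thresholds of a DR model
#'
#' Linear: the base temperature `T0 = -a/b`, where the response line crosses
#' zero. Multiple: `(T0m, P0m)`, the x-intercepts of the two univariate
#' projections of the fitted plane, each holding the other predictor at its
#' reference (training mean) value. Polynomial: the two real roots
#' `Tp1 < Tp2` of `a + b*T + c*T^2 = 0`, the cardinal temperatures between
#' which the rate is positive.
#'
#' @param model A [dr_model()].
#' @return A named list: `t0` (linear); `t0m`, `p0m` (multiple);
#'   `tp1`, `tp2` (polynomial).
#' @examples
#' critical_thresholds(dr_model("linear", -0.0253, 0.0031))$t0  # 8.16...
#' @export
critical_thresholds <- function(model) {
  stopifnot(inherits(model, "dr_model"))
  switch(model$kind,
    linear = {
      if (model$b == 0) {
        stop("base temperature undefined: b = 0", call. = FALSE)
      }
      list(t0 = -model$a / model$b)
    },
    multiple = {
      if (is.null(model$t_ref) || is.null(model$p_ref)) {
        stop("multiple model thresholds require reference values ",
             "t_ref and p_ref (training-sample means)", call. = FALSE)
      }
      if (model$b == 0 || model$c == 0) {
        stop("multiple model thresholds undefined: b or c is 0",
             call. = FALSE)
      }
      list(t0m = -(model$a + model$c * model$p_ref) / model$b,
           p0m = -(model$a + model$b * model$t_ref) / model$c)
    },
    polynomial = {
      if (model$c >= 0) {
        stop("polynomial DR model must be a downward parabola (c < 0) ",
             "to define cardinal temperatures", call. = FALSE)
      }
      disc <- model$b^2 - 4 * model$a * model$c
      if (disc < 0) {
        stop("polynomial DR model has no real roots: ",
             "cardinal temperatures undefined", call. = FALSE)
      }
      r <- sort((-model$b + c(-1, 1) * sqrt(disc)) / (2 * model$c))
      list(tp1 = r[1], tp2 = r[2])
    })
}

#' Linear DR response
#'
#' `DR = a + b*T` for temperatures strictly above the base temperature
#' `T0 = -a/b`; zero at or below it. Never negative.
#'
#' @param temp Daily mean air temperature(s), degrees C. Vectorised.
#' @param model A linear [dr_model()].
#' @return Developmental rate(s), d^-1.
#' @examples
#' m <- dr_model("linear", -0.0180, 0.0025)
#' dr_linear(20, m)  # 0.032
#' dr_linear(5, m)   # 0: below base temperature
#' @export
dr_linear <- function(temp, model) {
  stopifnot(inherits(model, "dr_model"))
  if (model$kind != "linear") {
    stop("dr_linear() requires a model of kind 'linear', got '",
         model$kind, "'", call. = FALSE)
  }
  ifelse(temp > model$thresholds$t0,
         pmax(model$a + model$b * temp, 0), 0)
}

#' Multiple linear DR response (temperature + daylength)
#'
#' `DR = a + b*T + c*P` when `T > T0m` and `P > P0m`; zero otherwise.
#'
#' @param temp Daily mean air temperature(s), degrees C.
#' @param daylength Daily daylength(s), hours. Recycled against `temp`.
#' @param model A multiple [dr_model()] with defined thresholds.
#' @return Developmental rate(s), d^-1, never negative.
#' @export
dr_multiple <- function(temp, daylength, model) {
  stopifnot(inherits(model, "dr_model"))
  if (model$kind != "multiple") {
    stop("dr_multiple() requires a model of kind 'multiple', got '",
         model$kind, "'", call. = FALSE)
  }
  th <- model$thresholds
  ifelse(temp > th$t0m & daylength > th$p0m,
         pmax(model$a + model$b * temp + model$c * daylength, 0), 0)
}

#' Polynomial DR response
#'
#' `DR = a + b*T + c*T^2` between the cardinal temperatures `Tp1 < Tp2`;
#' zero at or outside them. Development stops both below the lower and above
#' the upper cardinal temperature.
#'
#' @param temp Daily mean air temperature(s), degrees C.
#' @param model A polynomial [dr_model()] (downward parabola, two real
#'   roots).
#' @return Developmental rate(s), d^-1, never negative.
#' @export
dr_polynomial <- function(temp, model) {
  stopifnot(inherits(model, "dr_model"))
  if (model$kind != "polynomial") {
    stop("dr_polynomial() requires a model of kind 'polynomial', got '",
         model$kind, "'", call. = FALSE)
  }
  th <- model$thresholds
  ifelse(temp > th$tp1 & temp < th$tp2,
         pmax(model$a + model$b * temp + model$c * temp^2, 0), 0)
}

#' Evaluate a DR model on daily predictor values
#'
#' Dispatches to [dr_linear()], [dr_multiple()] or [dr_polynomial()]
#' according to the model kind.
#'
#' @param model A [dr_model()].
#' @param temp Daily mean air temperature(s), degrees C.
#' @param daylength Daily daylength(s), hours; required for the multiple
#'   kind only.
#' @return Developmental rate(s), d^-1.
#' @export
dr_rate <- function(model, temp, daylength = NULL) {
  switch(model$kind,
    linear = dr_linear(temp, model),
    multiple = {
      if (is.null(daylength)) {
        stop("multiple DR model requires daylength values", call. = FALSE)
      }
      dr_multiple(temp, daylength, model)
    },
    polynomial = dr_polynomial(temp, model))
}

#' @export
print.dr_model <- function(x, ...) {
  eqn <- switch(x$kind,
    linear = sprintf("DR = %.4g + %.4g T", x$a, x$b),
    multiple = sprintf("DR = %.4g + %.4g T + %.4g P", x$a, x$b, x$c),
    polynomial = sprintf("DR = %.4g + %.4g T + %.4g T^2", x$a, x$b, x$c))
  cat("<dr_model> kind:", x$kind, "\n  ", eqn, "\n", sep = "")
  th <- x$thresholds
  cat("  thresholds: ",
      paste(sprintf("%s = %.3g", names(th), unlist(th)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
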