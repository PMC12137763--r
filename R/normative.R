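#' Fit a polynomial mean trend against gestational age
#'
#' Ordinary least squares of the measure against GA, linear or quadratic.
#' Coefficients are returned in ascending powers (intercept first).
#'
#' @param ga Gestational ages in weeks (n >= 10, with spread).
#' @param value Measure values, same length.
#' @param trend `"linear"` or `"quadratic"`.
#' @return Numeric coefficient vector of length degree + 1.
#' @export
fit_trend <- function(ga, value, trend = c("linear", "quadratic")) {
  trend <- match.arg(trend)
  ga <- as.numeric(ga); value <- as.numeric(value)
  stopifnot(length(ga) == length(value))
  if (length(ga) < 10) stop("need at least 10 records to fit a trend",
                            call. = FALSE)
  if (sd(ga) == 0) stop("degenerate design: all gestational ages equal",
                        call. = FALSE)
  degree <- if (trend == "linear") 1L else 2L
  fit <- lm(value ~ poly(ga, degree, raw = TRUE))
  unname(coef(fit))
}

#' Fit a polynomial quantile curve against gestational age
#'
#' Quantile regression at level `tau`: minimizes the pinball (check) loss
#' \eqn{\sum_i \rho_\tau(y_i - X_i \beta)} over polynomial coefficients,
#' using the Barrodale-Roberts simplex solver of \pkg{quantreg}.
#' Deterministic given the data.
#'
#' @inheritParams fit_trend
#' @param tau Quantile level in (0, 1), e.g. 0.05 or 0.95.
#' @return Numeric coefficient vector in ascending powers.
#' @export
fit_quantile_curve <- function(ga, value, trend = c("linear", "quadratic"),
                               tau) {
  trend <- match.arg(trend)
  ga <- as.numeric(ga); value <- as.numeric(value)
  stopifnot(length(ga) == length(value))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single value in (0, 1)", call. = FALSE)
  if (length(ga) < 10) stop("need at least 10 records for quantile regression",
                            call. = FALSE)
  if (sd(ga) == 0) stop("degenerate design: all gestational ages equal",
                        call. = FALSE)
  degree <- if (trend == "linear") 1L else 2L
  fit <- quantreg::rq(value ~ poly(ga, degree, raw = TRUE), tau = tau,
                      method = "br")
  beta <- unname(coef(fit))
  if (any(!is.finite(beta)))
    stop("quantile regression failed to produce finite coefficients",
         call. = FALSE)
  beta
}

# evaluate polynomial with ascending-power coefficients
poly_eval <- function(coeffs, x) {
  y <- rep(0, length(x))
  for (k in seq_along(coeffs)) y <- y + coeffs[k] * x^(k - 1)
  y
}

new_normative_model <- function(organ, measure, trend, mean_coeffs,
                                q05_coeffs, q95_coeffs, ga_range, n_train) {
  m <- structure(list(organ = organ, measure = measure, trend = trend,
                      mean_coeffs = as.numeric(mean_coeffs),
                      q05_coeffs = as.numeric(q05_coeffs),
                      q95_coeffs = as.numeric(q95_coeffs),
                      ga_range = as.numeric(ga_range),
                      n_train = as.integer(n_train)),
                 class = "normative_model")
  grid <- seq(ga_range[1], ga_range[2], length.out = 101)
  if (any(poly_eval(m$q05_coeffs, grid) > poly_eval(m$q95_coeffs, grid)))
    warning("centile crossing detected for ", organ, "/", measure,
            " within the GA range", call. = FALSE)
  m
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model> ", x$organ, "/", x$measure, " (", x$trend,
      "), GA ", x$ga_range[1], "-", x$ga_range[2], " wk, n = ", x$n_train,
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a normative model's curves at given gestational ages
#'
#' @param object A `normative_model`.
#' @param ga_weeks Gestational ages in weeks.
#' @param what `"mean"`, `"q05"` or `"q95"`.
#' @param ... Unused.
#' @return Numeric vector of curve values.
#' @export
predict.normative_model <- function(object, ga_weeks,
                                    what = c("mean", "q05", "q95"), ...) {
  what <- match.arg(what)
  coeffs <- switch(what, mean = object$mean_coeffs,
                   q05 = object$q05_coeffs, q95 = object$q95_coeffs)
  poly_eval(coeffs, as.numeric(ga_weeks))
}

#' Build the full normative model set from a control table
#'
#' Fits, for every (organ, measure) combination present, the mean trend plus
#' 5th and 95th centile curves over gestational age. The trend is quadratic
#' for fetal-brain mean T2* and linear for the other three combinations
#' (placental mean T2*, and both volumes); the centile curves share the
#' trend's polynomial degree. Combinations with fewer than 10 rows are
#' omitted with a warning.
#'
#' @param table Data frame from [read_normative_table()] or
#'   [generate_control_cohort()].
#' @return Named list (`"organ.measure"`) of `normative_model` objects,
#'   class `normative_models`.
#' @export
build_normative_models <- function(table) {
  stopifnot(all(c("ga_weeks", "organ", "measure", "value") %in% names(table)))
  models <- list()
  for (org in ORGANS) {
    for (meas in MEASURES) {
      rows <- table[table$organ == org & table$measure == meas, ]
      key <- paste(org, meas, sep = ".")
      if (nrow(rows) < 10) {
        warning("insufficient rows (", nrow(rows), ") for ", key,
                "; model omitted", call. = FALSE)
        next
      }
      trend <- if (org == "fetal_brain" && meas == "mean_t2star")
        "quadratic" else "linear"
      models[[key]] <- new_normative_model(
        organ = org, measure = meas, trend = trend,
        mean_coeffs = fit_trend(rows$ga_weeks, rows$value, trend),
        q05_coeffs = fit_quantile_curve(rows$ga_weeks, rows$value, trend,
                                        tau = 0.05),
        q95_coeffs = fit_quantile_curve(rows$ga_weeks, rows$value, trend,
                                        tau = 0.95),
        ga_range = range(rows$ga_weeks), n_train = nrow(rows))
    }
  }
  if (length(models) == 0) stop("no model could be fitted from the table",
                                call. = FALSE)
  structure(models, class = "normative_models")
}

#' Serialize normative models to a versioned JSON document
#'
#' @param models A `normative_models` list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_normative_models <- function(models, path) {
  doc <- list(format = "fetalT2star-normative", version = 1L,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              models = lapply(unclass(models), unclass))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read normative models from JSON
#'
#' @param path JSON path written by [write_normative_models()].
#' @return A `normative_models` list.
#' @export
read_normative_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$models) || !identical(doc$format, "fetalT2star-normative"))
    stop("not a normative model store: ", path, call. = FALSE)
  models <- lapply(doc$models, function(m)
    new_normative_model(m$organ, m$measure, m$trend, m$mean_coeffs,
                        m$q05_coeffs, m$q95_coeffs, m$ga_range, m$n_train))
  structure(models, class = "normative_models")
}

#' Classify a measurement against a normative model
#'
#' Evaluates the 5th and 95th centile curves at the given gestational age
#' and assigns a band: `"low"` below the 5th centile, `"high"` above the
#' 95th, `"normal"` otherwise (band boundaries are inclusive: a value
#' exactly on a centile curve is normal). A GA outside the model's training
#' range is flagged `extrapolated` but still classified.
#'
#' @param model A `normative_model`.
#' @param ga_weeks Gestational age, decimal weeks.
#' @param value Measured value (same units as the model's measure).
#' @return An object of class `centile_result`.
#' @export
classify <- function(model, ga_weeks, value) {
  stopifnot(inherits(model, "normative_model"), is.finite(value))
  ga_weeks <- as.numeric(ga_weeks)
  q05 <- poly_eval(model$q05_coeffs, ga_weeks)
  q95 <- poly_eval(model$q95_coeffs, ga_weeks)
  band <- if (value < q05) "low" else if (value > q95) "high" else "normal"
  structure(list(organ = model$organ, measure = model$measure,
                 ga_weeks = ga_weeks, value = as.numeric(value),
                 q05_at_ga = q05, q95_at_ga = q95, band = band,
                 extrapolated = ga_weeks < model$ga_range[1] |
                   ga_weeks > model$ga_range[2]),
            class = "centile_result")
}

#' @export
print.centile_result <- function(x, ...) {
  cat(sprintf("<centile_result> %s/%s @ GA %.2f wk: %.2f -> %s (5th %.2f, 95th %.2f)%s\n",
              x$organ, x$measure, x$ga_weeks, x$value, x$band,
              x$q05_at_ga, x$q95_at_ga,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}
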