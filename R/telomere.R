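#' Read a qPCR CT plate
#'
#' CSV with columns `sample_id`, `run`, `target` (`T` or `S`), `replicate`,
#' `ct`. Calibrator wells (the reference cell line measured in every run)
#' carry the reserved sample id `"REF"`.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` of class `"ct_plate"`.
#' @export
read_ct_plate <- function(path) {
  ct_plate(utils::read.csv(path, check.names = FALSE))
}

#' CT plate constructor
#'
#' @param wells `data.frame` with columns `sample_id`, `run`, `target`,
#'   `replicate`, `ct` (cycles, positive).
#' @return `data.frame` of class `"ct_plate"`.
#' @export
ct_plate <- function(wells) {
  wells <- as.data.frame(wells)
  needed <- c("sample_id", "run", "target", "replicate", "ct")
  miss <- setdiff(needed, names(wells))
  if (length(miss)) stop("CT table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(wells$target %in% c("T", "S")))
    stop("target must be 'T' (telomere) or 'S' (single-copy gene)")
  if (any(wells$ct <= 0)) stop("CT values must be positive")
  class(wells) <- c("ct_plate", "data.frame")
  wells
}

#' T/S ratio for one sample and run
#'
#' Aggregates replicate CTs per target (arithmetic mean by default, median
#' optionally), forms `delta_ct = CT(T) - CT(S)` and returns the telomere to
#' single-copy-gene signal ratio `2^-delta_ct`.
#'
#' @param plate A [ct_plate()].
#' @param sample_id Sample to evaluate.
#' @param run Run number.
#' @param aggregate `"mean"` or `"median"` replicate aggregation.
#' @return Positive T/S value.
#' @examples
#' p <- ct_plate(data.frame(sample_id = "a", run = 1,
#'                          target = c("T", "S"), replicate = 1,
#'                          ct = c(21, 20)))
#' ts_ratio(p, "a", 1)  # delta CT 1 -> 0.5
#' @export
ts_ratio <- function(plate, sample_id, run, aggregate = c("mean", "median")) {
  stopifnot(inherits(plate, "ct_plate"))
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  sel <- plate$sample_id == sample_id & plate$run == run
  ct_t <- plate$ct[sel & plate$target == "T"]
  ct_s <- plate$ct[sel & plate$target == "S"]
  if (!length(ct_t) || !length(ct_s))
    stop("missing ", if (!length(ct_t)) "T" else "S",
         " wells for sample '", sample_id, "', run ", run)
  2^-(agg(ct_t) - agg(ct_s))
}

#' Relative telomere length from a CT plate
#'
#' Per run, the sample's T/S value is divided by the calibrator's T/S value
#' of the same run; the final RTL is the arithmetic mean over the runs in
#' which both are available. Runs lacking the calibrator are excluded with a
#' warning.
#'
#' @inheritParams ts_ratio
#' @param calibrator Reserved sample id of the calibrator line, default
#'   `"REF"`.
#' @return Positive RTL value.
#' @export
compute_rtl <- function(plate, sample_id, calibrator = "REF",
                        aggregate = c("mean", "median")) {
  stopifnot(inherits(plate, "ct_plate"))
  aggregate <- match.arg(aggregate)
  runs <- sort(unique(plate$run[plate$sample_id == sample_id]))
  if (!length(runs)) stop("no wells for sample '", sample_id, "'")
  per_run <- c()
  for (r in runs) {
    if (!any(plate$sample_id == calibrator & plate$run == r)) {
      warning("calibrator '", calibrator, "' missing in run ", r,
              "; run excluded for sample '", sample_id, "'")
      next
    }
    per_run <- c(per_run, ts_ratio(plate, sample_id, r, aggregate) /
                            ts_ratio(plate, calibrator, r, aggregate))
  }
  if (!length(per_run))
    stop("no usable runs for sample '", sample_id, "'")
  mean(per_run)
}

#' Fit the age-standardization model to a control cohort
#'
#' Double-LOESS model of relative telomere length against age in a healthy
#' control cohort: a first local regression of RTL on age gives the local
#' mean curve and its residuals; a second local regression of the squared
#' residuals on age gives the local variance, whose (floored) square root is
#' the local standard deviation. Case RTLs are then standardized as
#' `(rtl - mean_curve(age)) / sd_curve(age)` by [standardize_rtl()].
#'
#' The mean curve is fitted with span 0.75, locally quadratic, with robust
#' (bisquare) reweighting; the variance curve is fitted by plain least
#' squares, since robust weighting would systematically shrink the skewed
#' squared residuals and bias the local standard deviation downward. Fitted
#' local variances are floored at `var_floor` before the square root.
#'
#' @param controls `data.frame` with columns `age` (years) and `rtl`.
#' @param span LOESS span for both curves, default 0.75.
#' @param degree Local polynomial degree, default 2.
#' @param robust_iterations Robustness iterations for the mean curve,
#'   default 2.
#' @param var_floor Lower clamp for the fitted local variance, default 1e-8.
#' @return Object of class `"rtl_control_model"` with `predict`,
#'   `residuals`, `print`, `summary` and `plot` methods.
#' @export
fit_rtl_controls <- function(controls, span = 0.75, degree = 2,
                             robust_iterations = 2, var_floor = 1e-8) {
  controls <- as.data.frame(controls)
  stopifnot(all(c("age", "rtl") %in% names(controls)))
  controls <- controls[stats::complete.cases(controls[c("age", "rtl")]), ]
  if (nrow(controls) < 20L)
    stop("need at least 20 controls, got ", nrow(controls))
  if (diff(range(controls$age)) <= 0)
    stop("control ages are constant; cannot fit an age trend")
  mean_fit <- stats::loess(
    rtl ~ age, data = controls, span = span, degree = degree,
    family = "symmetric",
    control = stats::loess.control(surface = "direct",
                                   iterations = robust_iterations))
  res <- controls$rtl - stats::predict(mean_fit, controls$age)
  var_fit <- stats::loess(
    r2 ~ age, data = data.frame(age = controls$age, r2 = res^2),
    span = span, degree = degree, family = "gaussian",
    control = stats::loess.control(surface = "direct"))
  structure(
    list(mean_fit = mean_fit, var_fit = var_fit,
         controls = controls, residuals = res,
         age_support = range(controls$age),
         settings = list(span = span, degree = degree,
                         robust_iterations = robust_iterations,
                         var_floor = var_floor)),
    class = "rtl_control_model"
  )
}

#' Predict the control mean and SD curves
#'
#' Evaluates the fitted local mean and local standard deviation of control
#' RTL at given ages. Ages outside the control age support are clamped to the
#' nearest boundary rather than extrapolated.
#'
#' @param object An [fit_rtl_controls()] model.
#' @param age Numeric vector of ages (years).
#' @param ... Ignored.
#' @return `data.frame` with columns `age`, `mean`, `sd`.
#' @export
predict.rtl_control_model <- function(object, age, ...) {
  age_c <- pmin(pmax(age, object$age_support[1]), object$age_support[2])
  m <- stats::predict(object$mean_fit, age_c)
  v <- stats::predict(object$var_fit, age_c)
  s <- sqrt(pmax(v, object$settings$var_floor))
  data.frame(age = age, mean = m, sd = s)
}

#' @export
residuals.rtl_control_model <- function(object, ...) object$residuals

#' @export
print.rtl_control_model <- function(x, ...) {
  cat("Age-standardization model for relative telomere length\n")
  cat("  controls: n = ", nrow(x$controls), ", age ",
      x$age_support[1], "-", x$age_support[2], " years\n", sep = "")
  cat("  LOESS span ", x$settings$span, ", degree ", x$settings$degree,
      " (mean curve robust, ", x$settings$robust_iterations,
      " iterations; variance curve least squares)\n", sep = "")
  invisible(x)
}

#' @export
summary.rtl_control_model <- function(object, ...) {
  grid <- seq(object$age_support[1], object$age_support[2], length.out = 5)
  pr <- predict(object, grid)
  out <- list(n = nrow(object$controls), age_support = object$age_support,
              curve = pr, residual_sd = stats::sd(object$residuals),
              settings = object$settings)
  class(out) <- "summary.rtl_control_model"
  out
}

#' @export
print.summary.rtl_control_model <- function(x, ...) {
  cat("RTL control model: n =", x$n, " controls, age",
      x$age_support[1], "-", x$age_support[2], "\n")
  cat("raw residual SD:", format(x$residual_sd, digits = 4), "\n")
  cat("mean/SD curves at 5 support points:\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Plot the control cohort and fitted curves
#'
#' Scatter of control RTL against age with the fitted local mean and the
#' mean plus/minus 1, 2 and 3 local standard deviations.
#'
#' @param x An [fit_rtl_controls()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rtl_control_model <- function(x, ...) {
  ages <- seq(x$age_support[1], x$age_support[2], length.out = 200)
  pr <- predict(x, ages)
  graphics::plot(x$controls$age, x$controls$rtl, xlab = "age (years)",
                 ylab = "RTL", ...)
  graphics::lines(ages, pr$mean, lwd = 2)
  for (k in 1:3) {
    graphics::lines(ages, pr$mean + k * pr$sd, lty = 2)
    graphics::lines(ages, pr$mean - k * pr$sd, lty = 2)
  }
  invisible(x)
}

#' Age-standardized RTL residuals
#'
#' `rtl_sres = (rtl - mean_curve(age)) / sd_curve(age)` with both curves from
#' a fitted control model; ages outside the control support are evaluated at
#' the nearest boundary.
#'
#' @param rtl Numeric vector of case RTL values.
#' @param age Numeric vector of case ages (years), same length.
#' @param model An [fit_rtl_controls()] model.
#' @return Numeric vector of standardized residuals.
#' @export
standardize_rtl <- function(rtl, age, model) {
  if (!inherits(model, "rtl_control_model"))
    stop("model must be fitted with fit_rtl_controls()")
  stopifnot(length(rtl) == length(age))
  pr <- predict(model, age)
  (rtl - pr$mean) / pr$sd
}

#' Telomere length category from standardized residuals
#'
#' `short` iff `sres < -3`; `normal` iff `-3 <= sres <= 3`; `long` iff
#' `sres > 3`.
#'
#' @param sres Numeric vector of finite standardized residuals.
#' @return Factor with levels `short`, `normal`, `long`.
#' @examples
#' categorize_rtl(c(-3.1, -3, 0, 3, 3.3))
#' @export
categorize_rtl <- function(sres) {
  if (any(!is.finite(sres))) stop("non-finite standardized residual(s)")
  out <- ifelse(sres < -3, "short", ifelse(sres > 3, "long", "normal"))
  factor(out, levels = c("short", "normal", "long"))
}

#' Full CT-to-category telomere pipeline for a cohort
#'
#' Convenience wrapper: computes each case's RTL from the plate, fits (or
#' reuses) the control model and returns RTL, standardized residual and
#' category per case.
#'
#' @param plate A [ct_plate()] containing case and calibrator wells.
#' @param cases `data.frame` with columns `sample_id` and `age`.
#' @param controls Control cohort `data.frame` (`age`, `rtl`) or an already
#'   fitted [fit_rtl_controls()] model.
#' @inheritParams compute_rtl
#' @param ... Passed to [fit_rtl_controls()] when `controls` is a table.
#' @return `data.frame` of class `"rtl_result"`: `sample_id`, `rtl`, `age`,
#'   `rtl_sres`, `category`.
#' @export
rtl_pipeline <- function(plate, cases, controls, calibrator = "REF",
                         aggregate = c("mean", "median"), ...) {
  aggregate <- match.arg(aggregate)
  model <- if (inherits(controls, "rtl_control_model")) controls
           else fit_rtl_controls(controls, ...)
  rtl <- vapply(cases$sample_id, function(s)
    compute_rtl(plate, s, calibrator, aggregate), numeric(1L))
  sres <- standardize_rtl(rtl, cases$age, model)
  out <- data.frame(
    sample_id = cases$sample_id, rtl = rtl, age = cases$age,
    rtl_sres = sres, category = categorize_rtl(sres),
    row.names = NULL
  )
  class(out) <- c("rtl_result", "data.frame")
  attr(out, "model") <- model
  out
}
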