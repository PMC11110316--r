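#' Build a time-to-event table from a clinical sheet
#'
#' Derives disease-specific survival (DSS) or progression-free survival (PFS)
#' rows from a clinical sheet, optionally restricted to one treatment group.
#' DSS: time from diagnosis to death caused by lymphoma; deaths from other
#' causes censor at the death date; otherwise censored at last follow-up.
#' PFS: time from diagnosis to progression or relapse; otherwise censored at
#' death or last follow-up, whichever is first. Times are in years; rows with
#' a negative computed time are rejected into an `errors` attribute.
#'
#' @param clinical `data.frame` with columns `sample_id`, `entity`, `age`,
#'   `aaipi`, `treatment_group`, `time_death_years`, `death_cause`
#'   (`"lymphoma"`, `"other"` or `NA`), `time_progression_years`,
#'   `progression_flag`, `followup_years`.
#' @param endpoint `"dss"` or `"pfs"`.
#' @param treatment Treatment-group label to restrict to, or `NULL` for all
#'   patients. Default `"R-CHOP-like"`.
#' @param labels Optional `data.frame` of per-sample covariate labels
#'   (`sample_id` plus label columns, e.g. from [quantile_groups()],
#'   [classify_cimp()], [categorize_rtl()]), merged onto the table. Labels
#'   computed on the full cohort survive the treatment restriction, so
#'   full-cohort cutpoints can stratify a treated subset.
#' @return `data.frame` of class `"survival_table"` with columns `sample_id`,
#'   `time`, `event`, the clinical covariates, and any merged label columns.
#' @export
survival_table <- function(clinical, endpoint = c("dss", "pfs"),
                           treatment = "R-CHOP-like", labels = NULL) {
  endpoint <- match.arg(endpoint)
  clinical <- as.data.frame(clinical)
  needed <- c("sample_id", "time_death_years", "death_cause",
              "time_progression_years", "progression_flag", "followup_years")
  miss <- setdiff(needed, names(clinical))
  if (length(miss)) stop("clinical sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(treatment)) {
    if (!"treatment_group" %in% names(clinical))
      stop("clinical sheet lacks 'treatment_group'")
    clinical <- clinical[clinical$treatment_group %in% treatment, ,
                         drop = FALSE]
  }
  dead <- !is.na(clinical$time_death_years)
  if (endpoint == "dss") {
    event <- dead & clinical$death_cause %in% "lymphoma"
    time <- ifelse(dead, clinical$time_death_years, clinical$followup_years)
  } else {
    event <- clinical$progression_flag %in% TRUE
    censor_time <- ifelse(dead, pmin(clinical$time_death_years,
                                     clinical$followup_years, na.rm = TRUE),
                          clinical$followup_years)
    time <- ifelse(event, clinical$time_progression_years, censor_time)
  }
  bad <- !is.na(time) & time < 0
  out <- data.frame(sample_id = clinical$sample_id, time = time,
                    event = event, row.names = NULL)
  keep_cols <- intersect(c("entity", "age", "sex", "aaipi", "treatment_group"),
                         names(clinical))
  out <- cbind(out, clinical[keep_cols])
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (!"sample_id" %in% names(labels)) stop("labels need 'sample_id'")
    out <- merge(out, labels, by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  errors <- out[bad, , drop = FALSE]
  out <- out[!bad, , drop = FALSE]
  if (nrow(errors))
    warning(nrow(errors), " row(s) rejected for negative event time")
  rownames(out) <- NULL
  class(out) <- c("survival_table", "data.frame")
  attr(out, "endpoint") <- endpoint
  attr(out, "errors") <- errors
  out
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Kaplan-Meier median of the table with the event indicator inverted
#' (censorings become events, events become censorings) — the standard
#' estimator of median follow-up time. Not estimable when no observation is
#' censored.
#'
#' @param table A [survival_table()].
#' @return Median follow-up in years, or `NA` when not estimable.
#' @export
median_followup <- function(table) {
  stopifnot(inherits(table, "survival_table"), nrow(table) > 0)
  if (all(table$event))
    return(NA_real_)  # no censored observations: median follow-up undefined
  fit <- survival::survfit(
    survival::Surv(time, !event) ~ 1,
    data = data.frame(time = table$time, event = table$event))
  unname(summary(fit)$table["median"])
}

#' Univariable / multivariable proportional-hazards screening
#'
#' Cox proportional-hazards fits (Efron tie handling) of the endpoint in a
#' [survival_table()] against one or more categorical covariates, either one
#' model per covariate (`mode = "univariable"`, with a log-rank test per
#' covariate) or one joint model (`mode = "multivariable"`). Reference
#' levels can be set by supplying factors with the desired first level (see
#' [stats::relevel()]).
#'
#' @param table A [survival_table()].
#' @param covariates Character vector of covariate column names in `table`.
#' @param mode `"univariable"` or `"multivariable"`.
#' @return `data.frame` of class `"cox_screen"` with one row per
#'   non-reference covariate level: `covariate`, `level`, `n`, `events`,
#'   `hr`, `ci_low`, `ci_high`, `p_wald`, and (univariable mode) `p_logrank`.
#'   Attribute `fits` keeps the underlying `coxph` objects; `km` keeps a
#'   `survfit` Kaplan-Meier curve per covariate.
#' @export
fit_cox_models <- function(table, covariates,
                           mode = c("univariable", "multivariable")) {
  stopifnot(inherits(table, "survival_table"))
  mode <- match.arg(mode)
  miss <- setdiff(covariates, names(table))
  if (length(miss)) stop("covariate(s) not in table: ",
                         paste(miss, collapse = ", "))
  dat <- as.data.frame(table)
  for (cv in covariates) {
    dat[[cv]] <- droplevels(as.factor(dat[[cv]]))
    lev_n <- table(dat[[cv]])
    if (any(lev_n == 0)) stop("covariate '", cv, "' has an empty level")
  }
  surv_obj <- survival::Surv(dat$time, dat$event)

  extract <- function(fit, cv_names) {
    sm <- summary(fit)
    coefs <- sm$coefficients
    ci <- sm$conf.int
    rows <- lapply(cv_names, function(cv) {
      levs <- levels(dat[[cv]])[-1L]
      idx <- match(paste0(cv, levs), rownames(coefs))
      data.frame(
        covariate = cv, level = levs,
        n = as.integer(table(dat[[cv]])[levs]),
        events = as.integer(tapply(dat$event, dat[[cv]], sum)[levs]),
        hr = coefs[idx, "exp(coef)"],
        ci_low = ci[idx, "lower .95"],
        ci_high = ci[idx, "upper .95"],
        p_wald = coefs[idx, "Pr(>|z|)"],
        row.names = NULL)
    })
    do.call(rbind, rows)
  }

  fits <- list(); km <- list(); out <- NULL
  if (mode == "univariable") {
    for (cv in covariates) {
      f <- stats::as.formula(paste("surv_obj ~", cv))
      fit <- survival::coxph(f, data = dat, ties = "efron")
      zero_ev <- tapply(dat$event, dat[[cv]], sum) == 0
      if (any(zero_ev))
        warning("covariate '", cv, "': level(s) with zero events: ",
                paste(names(zero_ev)[zero_ev], collapse = ", "))
      lr <- survival::survdiff(f, data = dat)
      rows <- extract(fit, cv)
      rows$p_logrank <- stats::pchisq(lr$chisq, df = length(lr$n) - 1L,
                                      lower.tail = FALSE)
      fits[[cv]] <- fit
      km[[cv]] <- survival::survfit(f, data = dat)
      out <- rbind(out, rows)
    }
  } else {
    f <- stats::as.formula(paste("surv_obj ~",
                                 paste(covariates, collapse = " + ")))
    fit <- survival::coxph(f, data = dat, ties = "efron")
    for (cv in covariates) {
      zero_ev <- tapply(dat$event, dat[[cv]], sum) == 0
      if (any(zero_ev))
        warning("covariate '", cv, "': level(s) with zero events retained ",
                "in multivariable fit: ",
                paste(names(zero_ev)[zero_ev], collapse = ", "))
      km[[cv]] <- survival::survfit(
        stats::as.formula(paste("surv_obj ~", cv)), data = dat)
    }
    fits[["joint"]] <- fit
    out <- extract(fit, covariates)
  }
  class(out) <- c("cox_screen", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "endpoint") <- attr(table, "endpoint")
  attr(out, "fits") <- fits
  attr(out, "km") <- km
  out
}

#' @export
print.cox_screen <- function(x, digits = 3, ...) {
  cat("Proportional-hazards screen (", attr(x, "mode"), ", endpoint ",
      toupper(attr(x, "endpoint") %||% "?"), ")\n", sep = "")
  df <- as.data.frame(x)
  for (cl in c("hr", "ci_low", "ci_high", "p_wald", "p_logrank"))
    if (cl %in% names(df)) df[[cl]] <- signif(df[[cl]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
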