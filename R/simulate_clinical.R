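#' Clinical outcome simulation configuration
#'
#' Settings for [simulate_clinical()]. Disease-death times are exponential
#' with a group-specific hazard (`baseline_hazard` times the group's
#' multiplier), so the groups obey proportional hazards exactly. Progression
#' and other-cause death are independent exponentials scaled off the same
#' group hazard. Censoring combines an administrative horizon with a random
#' early-censoring fraction.
#'
#' @param hazard_multipliers Named positive vector, group label -> hazard
#'   ratio against baseline.
#' @param baseline_hazard Disease-death events per year in the reference
#'   group, default 0.08.
#' @param censoring_rate Fraction of subjects randomly censored before the
#'   horizon, default 0.2.
#' @param follow_up_horizon Administrative censoring time in years,
#'   default 17.
#' @param progression_ratio Progression hazard as a multiple of the group's
#'   death hazard, default 1.5.
#' @param other_cause_ratio Other-cause death hazard as a multiple of the
#'   group's death hazard, default 0.1.
#' @param seed Integer seed.
#' @return A list of class `"clinical_sim_config"`.
#' @export
clinical_sim_config <- function(hazard_multipliers = c(reference = 1),
                                baseline_hazard = 0.08,
                                censoring_rate = 0.2,
                                follow_up_horizon = 17,
                                progression_ratio = 1.5,
                                other_cause_ratio = 0.1,
                                seed = 1L) {
  if (is.null(names(hazard_multipliers)) || any(hazard_multipliers <= 0))
    stop("hazard_multipliers must be a named vector of positive ratios")
  stopifnot(baseline_hazard >= 0, censoring_rate >= 0, censoring_rate <= 1,
            follow_up_horizon > 0, progression_ratio >= 0,
            other_cause_ratio >= 0)
  structure(
    list(hazard_multipliers = hazard_multipliers,
         baseline_hazard = baseline_hazard,
         censoring_rate = censoring_rate,
         follow_up_horizon = follow_up_horizon,
         progression_ratio = progression_ratio,
         other_cause_ratio = other_cause_ratio,
         seed = as.integer(seed)),
    class = "clinical_sim_config"
  )
}

rexp_or_inf <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

#' Simulate a clinical outcome sheet
#'
#' One row per subject with entity (the group label), demographics, and the
#' outcome fields the survival module consumes: death time and cause,
#' progression time and flag, and follow-up time. Every subject's group
#' label must have a configured hazard multiplier.
#'
#' @param config A [clinical_sim_config()].
#' @param group_labels Character vector of group labels, one per subject.
#' @return `data.frame` with columns `sample_id`, `entity`, `age`, `sex`,
#'   `aaipi`, `treatment_group`, `time_death_years`, `death_cause`,
#'   `time_progression_years`, `progression_flag`, `followup_years`.
#' @examples
#' cfg <- clinical_sim_config(hazard_multipliers = c(A = 1, B = 3), seed = 2)
#' head(simulate_clinical(cfg, rep(c("A", "B"), each = 5)))
#' @export
simulate_clinical <- function(config, group_labels) {
  stopifnot(inherits(config, "clinical_sim_config"))
  group_labels <- as.character(group_labels)
  unknown <- setdiff(group_labels, names(config$hazard_multipliers))
  if (length(unknown))
    stop("group label(s) without a hazard multiplier: ",
         paste(unique(unknown), collapse = ", "))
  n <- length(group_labels)
  with_seed(config$seed, {
    h <- config$baseline_hazard * config$hazard_multipliers[group_labels]
    t_lymphoma <- vapply(h, function(r) rexp_or_inf(1L, r), numeric(1L))
    t_other <- vapply(h * config$other_cause_ratio,
                      function(r) rexp_or_inf(1L, r), numeric(1L))
    t_prog <- vapply(h * config$progression_ratio,
                     function(r) rexp_or_inf(1L, r), numeric(1L))
    censor <- rep(config$follow_up_horizon, n)
    early <- stats::runif(n) < config$censoring_rate
    censor[early] <- stats::runif(sum(early), 0, config$follow_up_horizon)

    t_death <- pmin(t_lymphoma, t_other)
    died <- t_death <= censor
    cause <- ifelse(t_lymphoma <= t_other, "lymphoma", "other")
    followup <- pmin(t_death, censor)
    progressed <- t_prog < followup

    data.frame(
      sample_id = sprintf("pt_%04d", seq_len(n)),
      entity = group_labels,
      age = round(stats::runif(n, 25, 89)),
      sex = sample(c("M", "F"), n, replace = TRUE),
      aaipi = sample(0:3, n, replace = TRUE,
                     prob = c(0.21, 0.35, 0.32, 0.12)),
      treatment_group = "R-CHOP-like",
      time_death_years = ifelse(died, t_death, NA_real_),
      death_cause = ifelse(died, cause, NA_character_),
      time_progression_years = ifelse(progressed, t_prog, NA_real_),
      progression_flag = progressed,
      followup_years = followup,
      row.names = NULL)
  })
}
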