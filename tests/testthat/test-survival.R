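clinical_fixture <- function() {
  data.frame(
    sample_id = paste0("p", 1:5),
    entity = "DLBCL-GC",
    age = 60, sex = "M", aaipi = 1,
    treatment_group = c(rep("R-CHOP-like", 4), "CNS"),
    time_death_years = c(2.0, 1.5, 2.0, NA, 3.0),
    death_cause = c("lymphoma", "other", "lymphoma", NA, "lymphoma"),
    time_progression_years = c(NA, NA, 0.5, NA, NA),
    progression_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    followup_years = c(2.0, 1.5, 2.0, 6.0, 3.0))
}

test_that("DSS events are lymphoma deaths; other deaths censor", {
  st <- survival_table(clinical_fixture(), "dss")
  expect_identical(nrow(st), 4L)  # CNS-treated patient excluded
  p1 <- st[st$sample_id == "p1", ]
  expect_equal(p1$time, 2.0); expect_true(p1$event)
  p2 <- st[st$sample_id == "p2", ]
  expect_equal(p2$time, 1.5); expect_false(p2$event)
  p4 <- st[st$sample_id == "p4", ]
  expect_equal(p4$time, 6.0); expect_false(p4$event)
})

test_that("PFS events are progression or relapse at the first event time", {
  st <- survival_table(clinical_fixture(), "pfs")
  p3 <- st[st$sample_id == "p3", ]
  expect_equal(p3$time, 0.5); expect_true(p3$event)
  # a death without progression censors PFS at the death date
  p1 <- st[st$sample_id == "p1", ]
  expect_equal(p1$time, 2.0); expect_false(p1$event)
})

test_that("negative times are rejected and labels merge by sample", {
  cl <- clinical_fixture()
  cl$followup_years[4] <- -1
  labels <- data.frame(sample_id = paste0("p", 1:5),
                       hypo_group = c("<Q1", ">Q3", "Q1-Q3", ">Q3", "<Q1"))
  expect_warning(st <- survival_table(cl, "dss", labels = labels),
                 "negative")
  expect_identical(nrow(st), 3L)
  expect_identical(st$hypo_group[st$sample_id == "p2"], ">Q3")
  expect_identical(nrow(attr(st, "errors")), 1L)
})

test_that("reverse Kaplan-Meier median follow-up handles the edge cases", {
  mk <- function(time, event) {
    cl <- data.frame(sample_id = seq_along(time), entity = "x",
                     treatment_group = "R-CHOP-like",
                     time_death_years = ifelse(event, time, NA),
                     death_cause = ifelse(event, "lymphoma", NA),
                     time_progression_years = NA, progression_flag = FALSE,
                     followup_years = time)
    survival_table(cl, "dss")
  }
  # everyone censored at 5 years -> median follow-up 5
  expect_equal(median_followup(mk(rep(5, 6), rep(FALSE, 6))), 5)
  # no censored observations -> not estimable
  expect_true(is.na(median_followup(mk(c(1, 2, 3), rep(TRUE, 3)))))
  # survivor function sits at 0.5 between 4 and 8: quantile convention
  # averages the interval endpoints (frozen from the survfit oracle)
  expect_equal(median_followup(mk(c(4, 4, 8, 8), rep(FALSE, 4))), 6)
  # fully censored at a common time: median equals that (maximum) time
  expect_equal(median_followup(mk(rep(9, 5), rep(FALSE, 5))), 9)
})

sim_table <- function(mult, n = 500, seed = 17, baseline = 0.2,
                      censoring = 0, horizon = 500) {
  cfg <- clinical_sim_config(hazard_multipliers = mult,
                             baseline_hazard = baseline,
                             censoring_rate = censoring,
                             follow_up_horizon = horizon,
                             other_cause_ratio = 0, seed = seed)
  cl <- simulate_clinical(cfg, rep(names(mult), each = n))
  survival_table(cl, "dss")
}

test_that("a null covariate gives a hazard ratio near one", {
  st <- sim_table(c(A = 1, B = 1), n = 300)
  fit <- fit_cox_models(st, "entity")
  expect_gt(fit$ci_high, 1)
  expect_lt(fit$ci_low, 1)
  expect_close(fit$hr, 1, 0.3)
})

test_that("a true hazard ratio of 3 is recovered at n = 500 per group", {
  st <- sim_table(c(A = 1, B = 3))
  fit <- fit_cox_models(st, "entity")
  expect_gt(fit$hr, 2.5)
  expect_lt(fit$hr, 3.6)
  expect_lt(fit$p_wald, 1e-6)
  expect_lt(fit$p_logrank, 1e-6)
})

test_that("univariable and multivariable fits coincide for one covariate", {
  st <- sim_table(c(A = 1, B = 2), n = 100, seed = 18)
  uni <- fit_cox_models(st, "entity", "univariable")
  multi <- fit_cox_models(st, "entity", "multivariable")
  expect_equal(uni$hr, multi$hr)
  expect_equal(uni$p_wald, multi$p_wald)
})

test_that("swapping the reference level inverts the hazard ratio", {
  st <- sim_table(c(A = 1, B = 2), n = 150, seed = 19)
  hr_ab <- fit_cox_models(st, "entity")$hr
  st$entity <- stats::relevel(factor(st$entity), ref = "B")
  hr_ba <- fit_cox_models(st, "entity")$hr
  expect_equal(hr_ba, 1 / hr_ab, tolerance = 1e-6)
})

test_that("multivariable fits adjust and warn on zero-event levels", {
  set.seed(20)
  cfg <- clinical_sim_config(hazard_multipliers = c(A = 1, B = 3),
                             baseline_hazard = 0.15, censoring_rate = 0.2,
                             follow_up_horizon = 15, seed = 20)
  cl <- simulate_clinical(cfg, rep(c("A", "B"), each = 250))
  cl$aaipi_group <- ifelse(cl$aaipi >= 2, "2-3", "0-1")
  st <- survival_table(cl, "dss",
                       labels = cl[c("sample_id", "aaipi_group")])
  fit <- fit_cox_models(st, c("entity", "aaipi_group"), "multivariable")
  expect_identical(nrow(fit), 2L)
  expect_gt(fit$hr[fit$covariate == "entity"], 1.5)
  # a level with no events still enters the fit, with a warning
  st2 <- st[c(1:30, (nrow(st) - 29):nrow(st)), ]
  class(st2) <- class(st)
  st2$event[st2$entity == "A"] <- FALSE
  # coxph additionally warns that the coefficient diverges; both expected
  w <- capture_warnings(fit_cox_models(st2, "entity", "multivariable"))
  expect_true(any(grepl("zero events", w)))
})

test_that("event-count orderings between endpoints hold by construction", {
  # every lymphoma death preceded by progression -> PFS events >= DSS events
  cl <- data.frame(
    sample_id = paste0("p", 1:6), entity = "x",
    treatment_group = "R-CHOP-like",
    time_death_years = c(2, 3, NA, NA, 4, NA),
    death_cause = c("lymphoma", "other", NA, NA, "lymphoma", NA),
    time_progression_years = c(1.5, NA, 2, NA, 3.5, NA),
    progression_flag = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    followup_years = c(2, 3, 5, 5, 4, 5))
  dss <- survival_table(cl, "dss")
  pfs <- survival_table(cl, "pfs")
  expect_lte(sum(dss$event), sum(!is.na(cl$time_death_years)))
  expect_gte(sum(pfs$event), sum(dss$event))
})
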