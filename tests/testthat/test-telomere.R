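plate_fixture <- function(ct_t, ct_s, sample_id = "a", run = 1) {
  ct_plate(data.frame(
    sample_id = sample_id, run = run,
    target = rep(c("T", "S"), c(length(ct_t), length(ct_s))),
    replicate = c(seq_along(ct_t), seq_along(ct_s)),
    ct = c(ct_t, ct_s)))
}

test_that("T/S follows 2^-deltaCT with replicate aggregation", {
  expect_equal(ts_ratio(plate_fixture(20, 20), "a", 1), 1)
  expect_equal(ts_ratio(plate_fixture(21, 20), "a", 1), 0.5)
  expect_equal(ts_ratio(plate_fixture(18, 20), "a", 1), 4)
  # triplicate means
  expect_equal(ts_ratio(plate_fixture(c(20.5, 21, 21.5), c(19.5, 20, 20.5)),
                        "a", 1), 0.5)
  # median aggregation resists one outlier replicate
  p <- plate_fixture(c(21, 21, 30), c(20, 20, 20))
  expect_equal(ts_ratio(p, "a", 1, aggregate = "median"), 0.5)
  expect_error(ts_ratio(plate_fixture(20, numeric(0)), "a", 1), "missing S")
})

test_that("each unit of deltaCT exactly halves the T/S value", {
  for (d in -4:4)
    expect_equal(ts_ratio(plate_fixture(20 + d, 20), "a", 1), 2^-d)
  for (d in 0:5)
    expect_equal(ts_ratio(plate_fixture(20 + d + 1, 20), "a", 1),
                 ts_ratio(plate_fixture(20 + d, 20), "a", 1) / 2)
})

test_that("RTL divides by the per-run calibrator and averages runs", {
  mk <- function(sample_dt, ref_dt, runs = 1:2) {
    rows <- do.call(rbind, lapply(runs, function(r) rbind(
      data.frame(sample_id = "a", run = r, target = c("T", "S"),
                 replicate = 1, ct = c(20 + sample_dt[r], 20)),
      data.frame(sample_id = "REF", run = r, target = c("T", "S"),
                 replicate = 1, ct = c(20 + ref_dt[r], 20)))))
    ct_plate(rows)
  }
  # sample equals calibrator in both runs -> RTL 1
  expect_equal(compute_rtl(mk(c(1, 2), c(1, 2)), "a"), 1)
  # run RTLs 0.8 and 1.2 average to 1
  p <- mk(c(1 - log2(0.8), 1 - log2(1.2)), c(1, 1))
  expect_equal(compute_rtl(p, "a"), 1)
  # single run
  expect_equal(compute_rtl(mk(c(2, NA), c(1, NA), runs = 1), "a"), 0.5)
  # calibrator missing in run 2: run dropped with a warning
  p2 <- mk(c(1, 1), c(1, 1))
  p2 <- ct_plate(p2[!(p2$sample_id == "REF" & p2$run == 2), ])
  expect_warning(r <- compute_rtl(p2, "a"), "calibrator")
  expect_equal(r, 1)
  expect_error(compute_rtl(mk(c(1, 1), c(1, 1)), "nope"), "no wells")
})

test_that("the control model reproduces a noiseless linear cohort", {
  controls <- data.frame(age = seq(0, 80, length.out = 60),
                         rtl = 1.4 - 0.008 * seq(0, 80, length.out = 60))
  m <- fit_rtl_controls(controls)
  expect_lt(max(abs(residuals(m))), 1e-9)
  # constant cohort too
  m2 <- fit_rtl_controls(data.frame(age = seq(0, 80, length.out = 40),
                                    rtl = rep(1.1, 40)))
  expect_lt(max(abs(residuals(m2))), 1e-9)
  expect_error(fit_rtl_controls(controls[1:10, ]), "at least 20")
  expect_error(fit_rtl_controls(data.frame(age = rep(40, 30),
                                           rtl = runif(30))), "constant")
})

test_that("a known constant noise SD is recovered across the age support", {
  set.seed(10)
  age <- runif(500, 0, 84)
  controls <- data.frame(age = age, rtl = 1.4 - 0.008 * age +
                           rnorm(500, 0, 0.2))
  m <- fit_rtl_controls(controls)
  grid <- seq(5, 79, by = 2)
  sd_hat <- predict(m, grid)$sd
  expect_true(all(abs(sd_hat - 0.2) / 0.2 < 0.10))
})

test_that("an age-increasing noise SD is recovered as increasing", {
  set.seed(11)
  age <- runif(600, 0, 84)
  sd_true <- 0.05 + 0.003 * age
  controls <- data.frame(age = age,
                         rtl = 1.4 - 0.008 * age + rnorm(600) * sd_true)
  m <- fit_rtl_controls(controls)
  grid <- seq(10, 74, by = 8)
  sd_hat <- predict(m, grid)$sd
  expect_true(all(diff(sd_hat) > 0))
})

test_that("standardized residuals and categories follow their definitions", {
  set.seed(12)
  age <- runif(200, 0, 84)
  controls <- data.frame(age = age, rtl = 1.3 - 0.006 * age +
                           rnorm(200, 0, 0.15))
  m <- fit_rtl_controls(controls)
  pr <- predict(m, c(30, 60))
  expect_equal(standardize_rtl(pr$mean, c(30, 60), m), c(0, 0),
               tolerance = 1e-9)
  expect_equal(standardize_rtl(pr$mean + 2 * pr$sd, c(30, 60), m), c(2, 2),
               tolerance = 1e-6)
  # out-of-support ages clamp to the boundary
  expect_equal(standardize_rtl(predict(m, 200)$mean, 200, m), 0,
               tolerance = 1e-9)
  expect_equal(predict(m, 200)$mean, predict(m, max(age))$mean)
  expect_error(standardize_rtl(1, 40, "not a model"), "fit_rtl_controls")

  expect_identical(as.character(categorize_rtl(c(-3.1, -3, 0, 3, 3.3))),
                   c("short", "normal", "normal", "normal", "long"))
  expect_error(categorize_rtl(c(1, NA)), "non-finite")
  x <- rnorm(100, 0, 3)
  expect_identical(sum(table(categorize_rtl(x))), 100L)
})

test_that("controls standardized against their own model are ~N(0,1)", {
  set.seed(13)
  age <- runif(500, 0, 84)
  controls <- data.frame(age = age, rtl = 1.4 - 0.008 * age +
                           rnorm(500) * (0.08 + 0.001 * age))
  m <- fit_rtl_controls(controls)
  sres <- standardize_rtl(controls$rtl, controls$age, m)
  expect_lt(abs(mean(sres)), 0.1)
  expect_lt(abs(sd(sres) - 1), 0.15)
})

test_that("zero-noise CT construction round-trips the target residuals", {
  targets <- c(-3.5, -1, 0, 1.5, 4, 10)
  sim <- simulate_telomere(telomere_sim_config(
    n_controls = 174, n_cases = length(targets),
    case_sres_targets = targets, ct_noise_sd = 0, seed = 14))
  res <- rtl_pipeline(sim$plate, sim$cases, sim$control_model)
  expect_equal(res$rtl_sres, targets, tolerance = 1e-6)
  expect_identical(as.character(res$category),
                   c("short", "normal", "normal", "normal", "long", "long"))
  # refitting from the emitted control table gives the same model
  m2 <- fit_rtl_controls(sim$controls)
  expect_equal(standardize_rtl(res$rtl, res$age, m2), targets,
               tolerance = 1e-6)
})

test_that("telomere simulation is deterministic and validates its config", {
  cfg <- telomere_sim_config(n_controls = 40, n_cases = 3,
                             case_sres_targets = c(-1, 0, 1), seed = 15)
  a <- simulate_telomere(cfg)
  b <- simulate_telomere(cfg)
  expect_identical(a$controls, b$controls)
  expect_identical(a$plate, b$plate)
  expect_error(telomere_sim_config(age_range = c(50, 50)), "age_range")
  expect_error(telomere_sim_config(sd_curve = function(a) 0.1 - 0.01 * a),
               "strictly positive")
  # constant-sd config: control residual SD close to the configured value
  sim <- simulate_telomere(telomere_sim_config(
    n_controls = 500, sd_curve = function(age) rep(0.2, length(age)),
    n_cases = 1, case_sres_targets = 0, seed = 16))
  res <- sim$controls$rtl - (1.35 - 0.008 * sim$controls$age)
  expect_lt(abs(sd(res) - 0.2) / 0.2, 0.10)
})
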