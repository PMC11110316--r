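#' Telomere simulation configuration
#'
#' Settings for [simulate_telomere()]. Defaults emulate the study's
#' measurement design: a 174-person control cohort spanning ages 0-84 with
#' an age-declining mean RTL and mildly age-increasing (heteroscedastic)
#' scatter, 93 cases whose intended standardized residuals span the reported
#' lymphoma range, qPCR triplicates in two runs, and a calibrator line
#' measured in every run.
#'
#' @param n_controls Number of controls, default 174.
#' @param age_range Control age range in years, default `c(0, 84)`.
#' @param mean_curve Decreasing function of age giving the mean control RTL.
#' @param sd_curve Strictly positive function of age giving the control SD.
#' @param n_cases Number of cases, default 93.
#' @param case_sres_targets Intended standardized residuals of the cases;
#'   default spans -4.7 to 18.9 (the reported lymphoma range). Recycled or
#'   truncated to `n_cases`.
#' @param ct_noise_sd Per-well CT noise SD in cycles, default 0.05.
#' @param seed Integer seed.
#' @return A list of class `"telomere_sim_config"`.
#' @export
telomere_sim_config <- function(
    n_controls = 174L, age_range = c(0, 84),
    mean_curve = function(age) 1.35 - 0.008 * age,
    sd_curve = function(age) 0.08 + 0.001 * age,
    n_cases = 93L,
    case_sres_targets = seq(-4.7, 18.9, length.out = n_cases),
    ct_noise_sd = 0.05, seed = 1L) {
  stopifnot(length(age_range) == 2L, is.function(mean_curve),
            is.function(sd_curve), ct_noise_sd >= 0)
  if (age_range[1] < 0 || diff(age_range) <= 0)
    stop("age_range must be non-degenerate with min >= 0")
  grid <- seq(age_range[1], age_range[2], length.out = 101)
  if (any(sd_curve(grid) <= 0))
    stop("sd_curve must be strictly positive over age_range")
  case_sres_targets <- rep_len(case_sres_targets, n_cases)
  structure(
    list(n_controls = as.integer(n_controls), age_range = age_range,
         mean_curve = mean_curve, sd_curve = sd_curve,
         n_cases = as.integer(n_cases),
         case_sres_targets = case_sres_targets,
         ct_noise_sd = ct_noise_sd, seed = as.integer(seed)),
    class = "telomere_sim_config"
  )
}

#' Simulate a control cohort and qPCR CT plate
#'
#' Generates (1) a control cohort table (`sample_id`, `age`, `rtl`) with
#' RTL = `mean_curve(age)` plus Gaussian noise scaled by `sd_curve(age)`;
#' (2) a [ct_plate()] with telomere (T) and single-copy-gene (S) triplicates
#' in two runs for every case plus calibrator wells (`"REF"`) in each run;
#' and (3) a case table (`sample_id`, `age`, `target_sres`).
#'
#' Case RTLs are placed at `mean + target_sres * sd` of the control model
#' *fitted* to the generated controls (default [fit_rtl_controls()]
#' settings), then inverted through `T/S = 2^-delta_ct` and the calibrator
#' division into CT values, so that the full CT -> RTL -> standardization
#' pipeline recovers the configured targets (exactly, at zero CT noise).
#'
#' @param config A [telomere_sim_config()].
#' @return List of class `"telomere_sim"` with elements `controls`, `plate`,
#'   `cases`, `reference` (the calibrator wells) and `control_model` (the
#'   internally fitted [fit_rtl_controls()] model).
#' @export
simulate_telomere <- function(config) {
  stopifnot(inherits(config, "telomere_sim_config"))
  with_seed(config$seed, {
    ages_c <- sort(stats::runif(config$n_controls, config$age_range[1],
                                config$age_range[2]))
    controls <- data.frame(
      sample_id = sprintf("ctrl_%03d", seq_len(config$n_controls)),
      age = ages_c,
      rtl = config$mean_curve(ages_c) +
        stats::rnorm(config$n_controls) * config$sd_curve(ages_c),
      row.names = NULL)

    model <- fit_rtl_controls(controls[c("age", "rtl")])

    ages_k <- stats::runif(config$n_cases, config$age_range[1],
                           config$age_range[2])
    pr <- predict(model, ages_k)
    rtl_k <- pr$mean + config$case_sres_targets * pr$sd
    if (any(rtl_k <= 0))
      stop("case construction produced non-positive RTL; ",
           "sres targets too extreme for the control curves")
    cases <- data.frame(
      sample_id = sprintf("case_%03d", seq_len(config$n_cases)),
      age = ages_k, target_sres = config$case_sres_targets,
      row.names = NULL)

    # invert RTL -> CT: per run, RTL = (T/S)_case / (T/S)_REF
    ref_ct_s <- 20; ref_delta <- 1          # REF T/S = 0.5
    run_offsets <- c(0, 0.35)               # run-level shift, cancelled by
                                            # the calibrator division
    wells <- list()
    noisy <- function(ct, n) rep(ct, each = n) +
      stats::rnorm(n * length(ct), 0, config$ct_noise_sd)
    for (run in 1:2) {
      off <- run_offsets[run]
      ref_ct_t <- ref_ct_s + ref_delta + off
      wells[[length(wells) + 1L]] <- data.frame(
        sample_id = "REF", run = run,
        target = rep(c("T", "S"), each = 3L), replicate = rep(1:3, 2L),
        ct = c(noisy(ref_ct_t, 3L), noisy(ref_ct_s, 3L)))
      case_ct_s <- rep(20, config$n_cases)
      case_ct_t <- case_ct_s + ref_delta + off - log2(rtl_k)
      wells[[length(wells) + 1L]] <- data.frame(
        sample_id = rep(cases$sample_id, each = 6L), run = run,
        target = rep(rep(c("T", "S"), each = 3L), config$n_cases),
        replicate = rep(1:3, 2L * config$n_cases),
        ct = as.vector(rbind(
          matrix(noisy(case_ct_t, 3L), nrow = 3L),
          matrix(noisy(case_ct_s, 3L), nrow = 3L))))
    }
    plate <- ct_plate(do.call(rbind, wells))
    structure(
      list(controls = controls, plate = plate, cases = cases,
           reference = plate[plate$sample_id == "REF", ],
           control_model = model),
      class = "telomere_sim")
  })
}
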