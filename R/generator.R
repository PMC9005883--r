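#' Configuration of the synthetic elite-rower cohort generator
#'
#' Population parameters of the mechanistic generator. Defaults describe a
#' cohort of heavyweight international-level male rowers: anthropometry and
#' maximal aerobic characteristics (mass 88.3 +/- 5.9 kg, height 1.91 +/-
#' 0.05 m, age 25.3 +/- 3.7 y, VO2max 5.67 +/- 0.36 L/min), an exponential
#' blood-lactate response la(W) = baseline + exp((W - onset)/shape) whose
#' default onset (328 W) and shape (55.5 W) place the 2 and 4 mmol/L
#' thresholds at 328 W and 328 + 55.5 ln 3 = 389 W, and a 2,000 m
#' performance near 6:00.
#'
#' Two latent standard-normal factors shape the correlation structure:
#' a size/fitness factor loading on mass, height and VO2max (inducing the
#' mass-performance correlation), and an oxidative-phenotype factor that
#' simultaneously lowers the VO2-vs-power slope (economy), delays lactate
#' onset, and lowers the RER curve (more fat oxidation) - so economical
#' rowers also show more fat use and less lactate, without any causal claim.
#' All standardised deviations are truncated at +/- `truncation` SD.
#'
#' @param n_subjects Cohort size. Default 21.
#' @param seed Integer RNG seed (same seed + config = identical output).
#' @param mass_mean,mass_sd,height_mean,height_sd,age_mean,age_sd
#'   Anthropometry, kg / m / years.
#' @param vo2max_mean,vo2max_sd Maximal oxygen uptake, mL/min.
#' @param vo2_rest_mean,vo2_rest_sd Intercept of the VO2-vs-power line,
#'   mL/min.
#' @param vo2_slope_mean,vo2_slope_sd Slope of the VO2-vs-power line,
#'   mL/min/W.
#' @param lactate_baseline Resting blood lactate, mmol/L.
#' @param lactate_onset_mean,lactate_onset_sd Onset parameter of the
#'   exponential lactate model, W.
#' @param lactate_shape Shape parameter, W (fixed across subjects so the
#'   threshold oracle stays closed-form).
#' @param lactate_lag_fraction Fraction of the within-step true lactate
#'   increment not yet visible in earlobe blood at the end of the step
#'   (muscle-to-blood transport inertia). Default 0.45; 0 disables the
#'   mechanism.
#' @param lactate_lag_onset Per-step true increment (mmol/L) below which
#'   blood fully equilibrates within the step; the lag applies only to the
#'   excess over this, so transport inertia shows on the surging final
#'   increments, not near the thresholds. Default 0.5.
#' @param lactate_lag_carry Fraction of the previous step's muscle-to-blood
#'   deficit still outstanding at the end of the next step (first-order
#'   transport kinetics; 0 means each step's deficit is fully equilibrated
#'   one step later). Default 0.6.
#' @param lactate_ceiling_mean,lactate_ceiling_sd True-lactate tolerance at
#'   which the subject fails the next step, mmol/L.
#' @param rer_base_mean,rer_base_sd,rer_ox_shift,rer_span,rer_exponent RER
#'   curve rer = base + span * u^exponent of relative intensity u =
#'   (aerobic demand)/VO2max; `rer_ox_shift` is the shift per SD of the
#'   oxidative-phenotype factor (negative: more oxidative, lower RER).
#' @param hr_rest,hr_max_mean,hr_max_sd Heart-rate curve endpoints, bpm.
#' @param anaerobic_capacity_per_kg,anaerobic_capacity_cv Anaerobic store,
#'   mLO2-equivalent per kg, and its coefficient of variation.
#' @param sustainable_fraction Fraction of VO2max sustainable over 2,000 m.
#' @param size_loading_mass,size_loading_height,size_loading_vo2max Loadings
#'   of the size/fitness factor.
#' @param ox_loading_slope,ox_loading_onset Loadings of the
#'   oxidative-phenotype factor on the (standardised) VO2 slope and lactate
#'   onset deviations.
#' @param vo2_noise_sd,vco2_noise_sd,lactate_noise_sd,hr_noise_sd
#'   Measurement noise SDs (mL/min, mL/min, mmol/L, bpm).
#' @param start_power,power_increment,work_s,rest_s Step protocol, W / W /
#'   s / s.
#' @param max_steps Hard cap on protocol length.
#' @param cap_overshoot_steps How many steps beyond the first VO2-capped
#'   step a subject can still complete. Default 1.
#' @param truncation Truncation of standardised deviations, in SD.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_subjects = 21, seed = 1,
    mass_mean = 88.3, mass_sd = 5.9,
    height_mean = 1.91, height_sd = 0.05,
    age_mean = 25.3, age_sd = 3.7,
    vo2max_mean = 5670, vo2max_sd = 360,
    vo2_rest_mean = 500, vo2_rest_sd = 30,
    vo2_slope_mean = 12.5, vo2_slope_sd = 0.5,
    lactate_baseline = 1.0,
    lactate_onset_mean = 328, lactate_onset_sd = 25,
    lactate_shape = 55.5,
    lactate_lag_fraction = 0.45,
    lactate_lag_onset = 0.5,
    lactate_lag_carry = 0.6,
    lactate_ceiling_mean = 15, lactate_ceiling_sd = 2,
    rer_base_mean = 0.78, rer_base_sd = 0.008,
    rer_ox_shift = -0.012, rer_span = 0.34, rer_exponent = 2.8,
    hr_rest = 70, hr_max_mean = 189, hr_max_sd = 8,
    anaerobic_capacity_per_kg = 65, anaerobic_capacity_cv = 0.08,
    sustainable_fraction = 0.98,
    size_loading_mass = 0.85, size_loading_height = 0.65,
    size_loading_vo2max = 0.8,
    ox_loading_slope = -0.6, ox_loading_onset = 0.75,
    vo2_noise_sd = 75, vco2_noise_sd = 90,
    lactate_noise_sd = 0.2, hr_noise_sd = 2,
    start_power = 200, power_increment = 50, work_s = 180, rest_s = 27,
    max_steps = 12, cap_overshoot_steps = 1,
    truncation = 3) {
  cfg <- as.list(environment())
  sds <- cfg[grepl("_sd$|_cv$", names(cfg))]
  if (any(unlist(sds) < 0)) {
    stop("generator_config: spreads (`*_sd`, `*_cv`) must be >= 0",
         call. = FALSE)
  }
  pos <- c("n_subjects", "mass_mean", "height_mean", "age_mean",
           "vo2max_mean", "vo2_rest_mean", "vo2_slope_mean",
           "lactate_onset_mean", "lactate_shape", "lactate_ceiling_mean",
           "anaerobic_capacity_per_kg", "sustainable_fraction",
           "start_power", "power_increment", "work_s", "truncation")
  for (p in pos) check_positive(cfg[[p]], p)
  check_probability(cfg$lactate_lag_fraction, "lactate_lag_fraction")
  for (ld in c("size_loading_mass", "size_loading_height",
               "size_loading_vo2max", "ox_loading_slope",
               "ox_loading_onset")) {
    if (abs(cfg[[ld]]) > 1) {
      stop(sprintf("`%s` must lie in [-1, 1]", ld), call. = FALSE)
    }
  }
  structure(cfg, class = "generator_config")
}

# standard normal truncated (clamped) at +/- b SD
rnorm_trunc <- function(n, b = 3) pmin(pmax(rnorm(n), -b), b)

# composite standardised deviation: loading * factor + residual, unit variance
load_on <- function(z, loading, b = 3) {
  res <- rnorm_trunc(length(z), b)
  loading * z + sqrt(1 - loading^2) * res
}

#' Draw a cohort of latent rower profiles
#'
#' Samples one [generator_config()] population: anthropometry plus the latent
#' physiological parameters of each subject (VO2 line, lactate curve, RER
#' curve, anaerobic store). Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with `profiles` (tibble, one row per subject, including the
#'   latent factors) and `subjects` (anthropometry table).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_subjects
  b <- config$truncation
  z_size <- rnorm_trunc(n, b)
  z_ox <- rnorm_trunc(n, b)

  mass <- config$mass_mean +
    config$mass_sd * load_on(z_size, config$size_loading_mass, b)
  height <- config$height_mean +
    config$height_sd * load_on(z_size, config$size_loading_height, b)
  age <- config$age_mean + config$age_sd * rnorm_trunc(n, b)
  vo2max <- config$vo2max_mean +
    config$vo2max_sd * load_on(z_size, config$size_loading_vo2max, b)
  vo2_rest <- config$vo2_rest_mean + config$vo2_rest_sd * rnorm_trunc(n, b)
  vo2_slope <- config$vo2_slope_mean +
    config$vo2_slope_sd * load_on(z_ox, config$ox_loading_slope, b)
  lactate_onset <- config$lactate_onset_mean +
    config$lactate_onset_sd * load_on(z_ox, config$ox_loading_onset, b)
  lactate_ceiling <- config$lactate_ceiling_mean +
    config$lactate_ceiling_sd * rnorm_trunc(n, b)
  rer_base <- config$rer_base_mean + config$rer_ox_shift * z_ox +
    config$rer_base_sd * rnorm_trunc(n, b)
  hr_max <- config$hr_max_mean + config$hr_max_sd * rnorm_trunc(n, b)
  anaerobic_capacity <- config$anaerobic_capacity_per_kg * mass *
    (1 + config$anaerobic_capacity_cv * rnorm_trunc(n, b))

  profiles <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    mass_kg = mass,
    height_m = height,
    age_yr = age,
    z_size = z_size,
    z_ox = z_ox,
    vo2_rest = vo2_rest,
    vo2_slope = vo2_slope,
    vo2max = vo2max,
    lactate_baseline = config$lactate_baseline,
    lactate_onset = lactate_onset,
    lactate_shape = config$lactate_shape,
    lactate_lag_fraction = config$lactate_lag_fraction,
    lactate_lag_onset = config$lactate_lag_onset,
    lactate_lag_carry = config$lactate_lag_carry,
    lactate_ceiling = lactate_ceiling,
    rer_base = rer_base,
    rer_span = config$rer_span,
    rer_exponent = config$rer_exponent,
    hr_rest = config$hr_rest,
    hr_max = hr_max,
    anaerobic_capacity = anaerobic_capacity,
    sustainable_fraction = config$sustainable_fraction
  )
  subjects <- profiles[c("subject_id", "mass_kg", "height_m", "age_yr")]
  list(profiles = profiles, subjects = subjects)
}

# true (muscle-compartment) lactate at end of a step at power W
true_lactate <- function(profile, power) {
  profile$lactate_baseline +
    exp((power - profile$lactate_onset) / profile$lactate_shape)
}

#' Simulate one incremental test to exhaustion
#'
#' Steps start at `start_power` and rise by `power_increment`. At each power
#' the aerobic demand is `vo2_rest + vo2_slope * W`, capped at the subject's
#' VO2max; true end-of-step lactate follows the exponential model. The test
#' ends when the next step would exceed the subject's lactate ceiling or run
#' more than `cap_overshoot_steps` beyond the first VO2-capped step; only
#' completed steps are emitted. Measured (earlobe) lactate is the true value
#' minus `lactate_lag_fraction` of the part of the current step's increment
#' exceeding `lactate_lag_onset`, plus assay noise: blood keeps pace with
#' slow accumulation but lags behind the surging increments of the final
#' steps (transport inertia), which is what flattens the measured ECR.
#'
#' @param profile One row of [generate_cohort()] profiles.
#' @param config The [generator_config()] used to draw it.
#' @param seed Optional seed for the measurement noise; when NULL the current
#'   RNG stream is used (as inside [simulate_study()]).
#' @return Tibble of completed steps in the on-disk `steps.csv` schema.
#' @export
simulate_incremental_test <- function(profile, config = generator_config(),
                                      seed = NULL) {
  run <- function() simulate_incremental_test_impl(profile, config)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_incremental_test_impl <- function(profile, config) {
  powers <- config$start_power +
    config$power_increment * (seq_len(config$max_steps) - 1)
  demand <- profile$vo2_rest + profile$vo2_slope * powers
  capped <- demand >= profile$vo2max
  la_true <- true_lactate(profile, powers)

  over_cap <- if (any(capped)) {
    seq_along(powers) > which(capped)[1] + config$cap_overshoot_steps
  } else {
    rep(FALSE, length(powers))
  }
  failed <- la_true > profile$lactate_ceiling | over_cap
  if (!any(failed)) {
    stop(sprintf(
      "simulate_incremental_test: subject %s reaches no exhaustion within %d steps",
      profile$subject_id, config$max_steps), call. = FALSE)
  }
  k <- which(failed)[1] - 1
  if (k < 2) {
    stop(sprintf(
      "simulate_incremental_test: subject %s completes fewer than 2 steps",
      profile$subject_id), call. = FALSE)
  }
  powers <- powers[seq_len(k)]
  demand <- demand[seq_len(k)]
  la_true <- la_true[seq_len(k)]

  vo2_true <- pmin(demand, profile$vo2max)
  vo2 <- vo2_true + rnorm(k, sd = config$vo2_noise_sd)
  u <- demand / profile$vo2max # relative intensity of the uncapped demand
  rer <- profile$rer_base + profile$rer_span * u^profile$rer_exponent
  vco2 <- rer * vo2_true + rnorm(k, sd = config$vco2_noise_sd)

  d_true <- diff(c(profile$lactate_baseline, la_true))
  new_deficit <- profile$lactate_lag_fraction *
    pmax(d_true - profile$lactate_lag_onset, 0)
  deficit <- numeric(k)
  for (j in seq_len(k)) {
    deficit[j] <- new_deficit[j] +
      if (j > 1) profile$lactate_lag_carry * deficit[j - 1] else 0
  }
  la_meas <- la_true - deficit + rnorm(k, sd = config$lactate_noise_sd)
  la_meas <- pmax(la_meas, 0.1)

  hr <- profile$hr_rest +
    (profile$hr_max - profile$hr_rest) * pmin(u, 1)^0.8 +
    rnorm(k, sd = config$hr_noise_sd)
  hr <- round(pmin(hr, profile$hr_max))

  tibble::tibble(
    subject_id = profile$subject_id,
    step_index = seq_len(k),
    power_w = powers,
    work_s = config$work_s,
    rest_s = config$rest_s,
    vo2_ml_min = vo2,
    vco2_ml_min = vco2,
    lactate_mmol_l = la_meas,
    hr_bpm = hr
  )
}

#' Simulate a 2,000 m all-out ergometer performance
#'
#' Race speed is the fixed point of the power-to-cost ratio
#' \eqn{v^* = \dot{E}(v^*) / C(v^*)}: sustainable metabolic power (a
#' fraction of VO2max plus the anaerobic store spread over the race
#' duration, mLO2/min) divided by the subject's energy cost per metre at
#' that speed (aerobic demand line extrapolated to race power, per metre).
#' Solved by damped fixed-point iteration on the cube-root rearrangement of
#' \eqn{v C(v) = \dot{E}(v)} (contractive because the drag term is cubic in
#' speed), to 1e-6 m/s.
#'
#' @inheritParams simulate_incremental_test
#' @param drag_constant Ergometer drag constant. Default 2.8.
#' @return List with `time_2000m_s` and `mean_speed_ms`.
#' @export
simulate_performance <- function(profile, config = generator_config(),
                                 drag_constant = 2.8) {
  available <- function(v_ms) {
    race_min <- 2000 / v_ms / 60
    profile$sustainable_fraction * profile$vo2max +
      profile$anaerobic_capacity / race_min
  }
  v <- 5 # m/s starting point
  damp <- 0.7
  k <- drag_constant * profile$vo2_slope
  for (i in seq_len(100)) {
    # v C(v) = E(v): cube-root rearrangement of the ratio equation
    v_new <- pmax((available(v) - profile$vo2_rest) / k, 1e-9)^(1 / 3)
    v_next <- v + damp * (v_new - v)
    if (abs(v_next - v) < 1e-6) {
      v <- v_next
      return(list(time_2000m_s = 2000 / v, mean_speed_ms = v))
    }
    v <- v_next
  }
  stop(sprintf(
    "simulate_performance: no convergence for subject %s (profile: vo2max=%.0f, slope=%.2f)",
    profile$subject_id, profile$vo2max, profile$vo2_slope), call. = FALSE)
}

#' Simulate a full study: cohort, incremental tests, performances
#'
#' One call produces everything the analysis pipeline consumes, byte-
#' deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List of class `rower_cohort`: `subjects` (with `time_2000m_s` and
#'   `speed_2000m_ms`), `steps` (all subjects' completed steps), and `truth`
#'   (the latent profiles, for parameter-recovery checks).
#' @examples
#' study <- simulate_study(generator_config(n_subjects = 5, seed = 42))
#' head(study$steps)
#' @export
simulate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    cohort <- generate_cohort_impl(config)
    steps <- dplyr::bind_rows(lapply(seq_len(config$n_subjects), function(i) {
      simulate_incremental_test_impl(cohort$profiles[i, ], config)
    }))
    perf <- lapply(seq_len(config$n_subjects), function(i) {
      simulate_performance(cohort$profiles[i, ], config)
    })
    subjects <- cohort$subjects
    subjects$time_2000m_s <- vapply(perf, `[[`, numeric(1), "time_2000m_s")
    subjects$speed_2000m_ms <- vapply(perf, `[[`, numeric(1),
                                      "mean_speed_ms")
    structure(list(subjects = subjects, steps = steps,
                   truth = cohort$profiles),
              class = "rower_cohort")
  })
}
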