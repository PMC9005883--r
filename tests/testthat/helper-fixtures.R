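# Shared fixtures, built in code.

# a deterministic, noise-free single-subject incremental test constructed
# directly from the generator's mechanistic model
noiseless_config <- function(...) {
  generator_config(
    n_subjects = 1, seed = 1,
    mass_sd = 0, height_sd = 0, age_sd = 0, vo2max_sd = 0, vo2_rest_sd = 0,
    vo2_slope_sd = 0, lactate_onset_sd = 0, lactate_ceiling_sd = 0,
    rer_base_sd = 0, hr_max_sd = 0, anaerobic_capacity_cv = 0,
    vo2_noise_sd = 0, vco2_noise_sd = 0, lactate_noise_sd = 0,
    hr_noise_sd = 0,
    ...
  )
}

# small hand-built two-subject cohort for interface tests
tiny_cohort_files <- function(dir) {
  subjects <- data.frame(
    subject_id = c("A", "B"), mass_kg = c(85, 92),
    height_m = c(1.88, 1.95), age_yr = c(24, 28),
    time_2000m_s = c(362, 355)
  )
  steps <- expand.grid(subject_id = c("A", "B"), step_index = 1:4)
  steps$power_w <- 200 + 50 * (steps$step_index - 1)
  steps$work_s <- 180
  steps$rest_s <- 27
  steps$vo2_ml_min <- 500 + 12.5 * steps$power_w
  steps$vco2_ml_min <- 0.9 * steps$vo2_ml_min
  steps$lactate_mmol_l <- 1 + exp((steps$power_w - 328) / 55.5)
  steps$hr_bpm <- 120 + 0.15 * steps$power_w
  steps <- steps[order(steps$subject_id, steps$step_index), ]
  write.csv(subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(steps, file.path(dir, "steps.csv"), row.names = FALSE)
  list(subjects = file.path(dir, "subjects.csv"),
       steps = file.path(dir, "steps.csv"))
}
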