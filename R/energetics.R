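#' Energy cost of rowing for one step
#'
#' The ECR statistic: oxygen-equivalent energy per metre,
#' \deqn{ECR = \frac{\dot{V}O_2 + (d[La^-]_b/dt) \times 3.3 \times mass}
#'                  {mean\ step\ speed}}
#' with \eqn{\dot{V}O_2} in mL/min, the blood-lactate accumulation rate in
#' mmol/L/min converted to an oxygen equivalent with 3.3 mLO2 per kg per
#' mmol/L, and speed in m/min. Net lactate clearance (negative accumulation)
#' is floored at zero by default: the oxygen equivalent models the
#' non-oxidative glycolytic contribution, and lactate that is cleared by
#' oxidation is already counted in \eqn{\dot{V}O_2}.
#'
#' @param vo2 Oxygen uptake, mL/min (> 0).
#' @param delta_lactate Blood lactate change over the step, mmol/L.
#' @param dt Time base of the accumulation, minutes (> 0).
#' @param mass Body mass, kg (> 0).
#' @param speed Mean step speed, m/min (> 0).
#' @param lactate_o2_equivalent mLO2 per kg per mmol/L. Default 3.3.
#' @param lactate_floor Floor negative accumulation rates at 0? Default TRUE.
#' @return Tibble with `ecr_abs` (mLO2/m), `ecr_per_kg` (mLO2/kg/m),
#'   `lactate_rate` (raw, mmol/L/min) and `anaerobic_o2_equiv` (mL/min).
#' @examples
#' step_ecr(vo2 = 5000, delta_lactate = 1, dt = 3, mass = 88, speed = 300)
#' @export
step_ecr <- function(vo2, delta_lactate, dt, mass, speed,
                     lactate_o2_equivalent = 3.3, lactate_floor = TRUE) {
  check_positive(vo2, "vo2")
  check_number(delta_lactate, "delta_lactate")
  check_positive(dt, "dt")
  check_positive(mass, "mass")
  check_positive(speed, "speed")
  check_positive(lactate_o2_equivalent, "lactate_o2_equivalent")
  rate <- delta_lactate / dt
  eff_rate <- if (lactate_floor) pmax(rate, 0) else rate
  anaerobic <- eff_rate * lactate_o2_equivalent * mass
  ecr_abs <- (vo2 + anaerobic) / speed
  tibble::tibble(
    ecr_abs = ecr_abs,
    ecr_per_kg = ecr_abs / mass,
    lactate_rate = rate,
    anaerobic_o2_equiv = anaerobic
  )
}

#' Per-step ECR profile of one subject
#'
#' Derives, for every completed step of an incremental test, the speed and
#' distance (cube-law drag model), the lactate accumulation relative to the
#' previous step (relative to `baseline_lactate` for the first step), the
#' substrate-oxidation partitioning, and the ECR.
#'
#' @param steps Data frame of one subject's steps with columns `power_w`,
#'   `work_s`, `vo2_ml_min`, `vco2_ml_min`, `lactate_mmol_l`, and optionally
#'   `step_index`, `rest_s`, `hr_bpm`, `subject_id`.
#' @param mass Body mass in kg.
#' @param config An [analysis_config()].
#' @return Tibble, one row per step: identifiers, `speed_ms`, `speed_m_min`,
#'   `distance_m`, `delta_lactate`, `lactate_rate`, `anaerobic_o2_equiv`,
#'   `ecr_abs`, `ecr_per_kg`, `rer`, and the [substrate_oxidation()] columns.
#' @export
ecr_profile <- function(steps, mass, config = analysis_config()) {
  steps <- as.data.frame(steps)
  required <- c("power_w", "work_s", "vo2_ml_min", "vco2_ml_min",
                "lactate_mmol_l")
  missing_cols <- setdiff(required, names(steps))
  if (length(missing_cols) > 0) {
    stop("ecr_profile: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(steps) < 2) {
    stop("ecr_profile: need at least 2 completed steps (got ", nrow(steps),
         ")", call. = FALSE)
  }
  if (anyNA(steps$lactate_mmol_l)) {
    bad <- which(is.na(steps$lactate_mmol_l))
    who <- if ("subject_id" %in% names(steps)) steps$subject_id[1] else "?"
    stop(sprintf("ecr_profile: missing lactate for subject %s at step(s) %s",
                 who, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.unsorted(steps$power_w, strictly = TRUE)) {
    stop("ecr_profile: step powers must be strictly increasing",
         call. = FALSE)
  }
  check_positive(mass, "mass")

  pace <- power_to_pace(steps$power_w, config$drag_constant)
  speed_ms <- 1 / pace
  speed_m_min <- 60 * speed_ms
  distance_m <- steps$work_s * speed_ms

  prev_la <- c(config$baseline_lactate, steps$lactate_mmol_l[-nrow(steps)])
  delta_la <- steps$lactate_mmol_l - prev_la
  dt_s <- steps$work_s +
    if (isTRUE(config$include_rest_in_dt) && "rest_s" %in% names(steps)) {
      steps$rest_s
    } else {
      0
    }
  ecr <- step_ecr(steps$vo2_ml_min, delta_la, dt_s / 60, mass, speed_m_min,
                  lactate_o2_equivalent = config$lactate_o2_equivalent,
                  lactate_floor = config$lactate_floor)
  subs <- substrate_oxidation(steps$vo2_ml_min / 1000,
                              steps$vco2_ml_min / 1000)

  out <- tibble::tibble(
    step_index = steps$step_index %||% seq_len(nrow(steps)),
    power_w = steps$power_w,
    work_s = steps$work_s,
    speed_ms = speed_ms,
    speed_m_min = speed_m_min,
    distance_m = distance_m,
    vo2_ml_min = steps$vo2_ml_min,
    vco2_ml_min = steps$vco2_ml_min,
    rer = steps$vco2_ml_min / steps$vo2_ml_min,
    lactate_mmol_l = steps$lactate_mmol_l,
    delta_lactate = delta_la
  )
  out <- dplyr::bind_cols(out, ecr[c("lactate_rate", "anaerobic_o2_equiv",
                                     "ecr_abs", "ecr_per_kg")], subs)
  if ("subject_id" %in% names(steps)) {
    out <- dplyr::bind_cols(
      tibble::tibble(subject_id = steps$subject_id), out
    )
  }
  if ("hr_bpm" %in% names(steps)) out$hr_bpm <- steps$hr_bpm
  out
}

#' Subject-level maximal ECR
#'
#' The highest per-kg ECR reached over the completed steps of the incremental
#' test.
#'
#' @param metrics An [ecr_profile()] result (needs column `ecr_per_kg`).
#' @return Maximal `ecr_per_kg`, mLO2/kg/m.
#' @export
subject_ecr_max <- function(metrics) {
  if (is.null(metrics$ecr_per_kg) || nrow(metrics) == 0) {
    stop("subject_ecr_max: empty or invalid ECR profile", call. = FALSE)
  }
  max(metrics$ecr_per_kg)
}
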