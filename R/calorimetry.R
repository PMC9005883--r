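#' Mixed-expired gas sample
#'
#' A timed collection of mixed expired air (e.g. from a Tissot spirometer fed
#' by a mixing chamber), with the ambient conditions needed to standardise the
#' volume. `volume_convention` states how `expired_volume` was measured:
#' `"atps"` (ambient temperature and pressure, saturated — the raw spirometer
#' reading) triggers an ATPS-to-STPD correction using the Magnus saturation
#' vapour-pressure formula; `"stpd"` means the volume is already standard
#' temperature and pressure, dry, and is used as-is.
#'
#' @param fe_o2,fe_co2 Mixed-expired O2 and CO2 fractions (0-1); their sum
#'   must be < 1.
#' @param expired_volume Expired volume over the window, litres.
#' @param window_duration Collection window, seconds.
#' @param ambient_temp Spirometer temperature, degrees C (used for `"atps"`).
#' @param barometric_pressure Barometric pressure, mmHg.
#' @param fi_o2,fi_co2 Inspired fractions; room-air defaults 0.2093 / 0.0004.
#' @param volume_convention `"atps"` or `"stpd"`.
#' @return A `gas_sample` list.
#' @seealso [gas_exchange_from_sample()]
#' @export
gas_sample <- function(fe_o2, fe_co2, expired_volume, window_duration,
                       ambient_temp = 20, barometric_pressure = 760,
                       fi_o2 = 0.2093, fi_co2 = 0.0004,
                       volume_convention = c("atps", "stpd")) {
  volume_convention <- match.arg(volume_convention)
  check_probability(fe_o2, "fe_o2")
  check_probability(fe_co2, "fe_co2")
  if (fe_o2 + fe_co2 >= 1) {
    stop("`fe_o2` + `fe_co2` must be < 1", call. = FALSE)
  }
  check_positive(expired_volume, "expired_volume")
  check_positive(window_duration, "window_duration")
  check_positive(barometric_pressure, "barometric_pressure")
  check_number(ambient_temp, "ambient_temp")
  check_probability(fi_o2, "fi_o2")
  check_probability(fi_co2, "fi_co2")
  structure(
    list(fe_o2 = fe_o2, fe_co2 = fe_co2,
         expired_volume = expired_volume, window_duration = window_duration,
         ambient_temp = ambient_temp,
         barometric_pressure = barometric_pressure,
         fi_o2 = fi_o2, fi_co2 = fi_co2,
         volume_convention = volume_convention),
    class = "gas_sample"
  )
}

# Saturation water vapour pressure in mmHg (Magnus formula, t in degrees C).
saturation_vapour_pressure <- function(t) {
  6.1078 * 10^(7.5 * t / (t + 237.3)) * 0.750062
}

#' Oxygen uptake and CO2 output from a mixed-expired sample
#'
#' Standard open-circuit calculation: the expired ventilation is standardised
#' to STPD, the inspired ventilation is inferred from nitrogen conservation
#' (Haldane transform, \eqn{\dot{V}_I = \dot{V}_E F_{E}N_2 / F_{I}N_2} with
#' \eqn{FN_2 = 1 - FO_2 - FCO_2}), and
#' \deqn{\dot{V}O_2 = \dot{V}_I F_IO_2 - \dot{V}_E F_EO_2, \qquad
#'       \dot{V}CO_2 = \dot{V}_E F_ECO_2 - \dot{V}_I F_ICO_2.}
#'
#' @param sample A [gas_sample()].
#' @return A one-row tibble with `vo2_ml_min`, `vco2_ml_min` (STPD) and `rer`.
#' @examples
#' s <- gas_sample(0.17, 0.04, expired_volume = 100, window_duration = 60,
#'                 volume_convention = "stpd")
#' gas_exchange_from_sample(s)
#' @export
gas_exchange_from_sample <- function(sample) {
  stopifnot(inherits(sample, "gas_sample"))
  ve <- sample$expired_volume / (sample$window_duration / 60) # L/min as given
  if (sample$volume_convention == "atps") {
    ph2o <- saturation_vapour_pressure(sample$ambient_temp)
    ve <- ve * (sample$barometric_pressure - ph2o) / 760 *
      273.15 / (273.15 + sample$ambient_temp)
  }
  fe_n2 <- 1 - sample$fe_o2 - sample$fe_co2
  fi_n2 <- 1 - sample$fi_o2 - sample$fi_co2
  vi <- ve * fe_n2 / fi_n2
  vo2 <- vi * sample$fi_o2 - ve * sample$fe_o2   # L/min STPD
  vco2 <- ve * sample$fe_co2 - vi * sample$fi_co2
  if (vo2 <= 0) {
    stop("degenerate gas sample: computed oxygen uptake is not positive",
         call. = FALSE)
  }
  tibble::tibble(
    vo2_ml_min = 1000 * vo2,
    vco2_ml_min = 1000 * vco2,
    rer = vco2 / vo2
  )
}

#' Respiratory exchange ratio
#'
#' @param vo2 Oxygen uptake (> 0), any unit.
#' @param vco2 CO2 output (>= 0), same unit.
#' @return `vco2 / vo2`, unclamped: values above 1 occur near exhaustion when
#'   bicarbonate buffering of lactic acidosis adds non-metabolic CO2.
#' @export
respiratory_exchange_ratio <- function(vo2, vco2) {
  check_positive(vo2, "vo2")
  check_non_negative(vco2, "vco2")
  vco2 / vo2
}

# Stoichiometric constants of the indirect-calorimetry partitioning:
# gram rates g/min = vo2*a - vco2*b, converted to kcal/min with the energetic
# equivalents 9.75 kcal/g (fat) and 4.07 kcal/g (carbohydrate).
FAT_O2_COEF <- 1.695
FAT_CO2_COEF <- 1.701
CHO_CO2_COEF <- 4.585
CHO_O2_COEF <- 3.226
FAT_KCAL_PER_G <- 9.75
CHO_KCAL_PER_G <- 4.07

#' Substrate oxidation rates from gas exchange
#'
#' Indirect-calorimetry partitioning of whole-body fuel use (protein assumed
#' negligible):
#' \deqn{Fat (kcal/min) = (1.695\,\dot{V}O_2 - 1.701\,\dot{V}CO_2) \times 9.75}
#' \deqn{CHO (kcal/min) = (4.585\,\dot{V}CO_2 - 3.226\,\dot{V}O_2) \times 4.07}
#' Raw rates are returned untouched (they go negative outside the RER range
#' 0.7036-0.9965, e.g. during buffering-driven hyperventilation); the fat
#' fraction of energy supply is computed on rates clipped at zero, with
#' `clipped` flagging when that happened.
#'
#' @param vo2 Oxygen uptake, L/min (vectorised, > 0).
#' @param vco2 CO2 output, L/min (>= 0).
#' @return Tibble with `fat_kcal_min`, `cho_kcal_min`, `fat_g_min`,
#'   `cho_g_min`, `fat_fraction` and `clipped`.
#' @examples
#' substrate_oxidation(4.0, 3.6)
#' @export
substrate_oxidation <- function(vo2, vco2) {
  check_positive(vo2, "vo2")
  check_non_negative(vco2, "vco2")
  stopifnot(length(vo2) == length(vco2))
  fat_kcal <- (vo2 * FAT_O2_COEF - vco2 * FAT_CO2_COEF) * FAT_KCAL_PER_G
  cho_kcal <- (vco2 * CHO_CO2_COEF - vo2 * CHO_O2_COEF) * CHO_KCAL_PER_G
  fat_pos <- pmax(fat_kcal, 0)
  cho_pos <- pmax(cho_kcal, 0)
  total <- fat_pos + cho_pos
  tibble::tibble(
    fat_kcal_min = fat_kcal,
    cho_kcal_min = cho_kcal,
    fat_g_min = fat_kcal / FAT_KCAL_PER_G,
    cho_g_min = cho_kcal / CHO_KCAL_PER_G,
    fat_fraction = ifelse(total > 0, fat_pos / total, NA_real_),
    clipped = fat_kcal < 0 | cho_kcal < 0
  )
}
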