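#' Polynomial blood lactate vs power curve
#'
#' Least-squares polynomial fit of end-of-step blood lactate against step
#' power, used to interpolate the powers at fixed lactate concentrations
#' (2 and 4 mmol/L). The fit is valid only over the observed power range;
#' evaluations outside it are flagged as extrapolation by the threshold
#' search.
#'
#' @param powers Step powers, watts, strictly increasing.
#' @param lactates End-of-step lactate, mmol/L, same length.
#' @param degree Polynomial degree (default 3).
#' @return A `lactate_curve` with `coefficients` (ascending powers),
#'   `fit_domain`, `degree`, `residuals`.
#' @export
fit_lactate_curve <- function(powers, lactates, degree = 3) {
  check_positive(powers, "powers")
  check_non_negative(lactates, "lactates")
  if (length(powers) != length(lactates)) {
    stop("`powers` and `lactates` must have equal length", call. = FALSE)
  }
  if (is.unsorted(powers, strictly = TRUE)) {
    stop("`powers` must be strictly increasing", call. = FALSE)
  }
  if (length(powers) < degree + 1) {
    stop(sprintf(paste0(
      "fit_lactate_curve: %d points cannot support degree %d ",
      "(need >= %d); reduce `degree`"),
      length(powers), degree, degree + 1), call. = FALSE)
  }
  # centre/scale power for numerical conditioning, store raw-scale coefs
  mu <- mean(powers)
  sc <- max(sd(powers), 1)
  x <- (powers - mu) / sc
  fit <- lm(lactates ~ poly(x, degree, raw = TRUE))
  structure(
    list(
      coefficients = unname(coef(fit)),
      center = mu, scale = sc, degree = degree,
      fit_domain = range(powers),
      residuals = unname(fit$residuals)
    ),
    class = "lactate_curve"
  )
}

#' @export
predict.lactate_curve <- function(object, power, ...) {
  x <- (power - object$center) / object$scale
  drop(outer(x, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.lactate_curve <- function(x, ...) {
  cat(sprintf("<lactate_curve> degree %d over [%g, %g] W, RMSE %.3g mmol/L\n",
              x$degree, x$fit_domain[1], x$fit_domain[2],
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Interpolate a lactate threshold from a fitted curve
#'
#' Finds the lowest power at which the fitted lactate polynomial crosses the
#' target concentration on a rising segment, by bracketed root finding on a
#' fine grid over the fit domain extended by one step width. Crossings on
#' falling segments (artefacts of a wiggly polynomial) are ignored.
#' Cardioventilatory values at the threshold power come from linear fits
#' against power supplied by the caller, not from the lactate polynomial.
#'
#' @param curve A [fit_lactate_curve()] result.
#' @param target Target lactate, mmol/L (> 0), conventionally 2 or 4.
#' @param vo2_fit,hr_fit Optional functions of power returning VO2 (mL/min)
#'   and HR (bpm) at a power, e.g. from [submaximal_linear_fit()].
#' @param step_width Protocol increment in watts, sets how far beyond the
#'   observed range the search may extrapolate. Default 50.
#' @param tol Root tolerance in watts. Default 1e-6.
#' @return One-row tibble: `target_lactate`, `power_w`, `vo2_ml_min`,
#'   `hr_bpm` (NA when no fit is given), `extrapolated`.
#' @export
interpolate_threshold <- function(curve, target, vo2_fit = NULL,
                                  hr_fit = NULL, step_width = 50,
                                  tol = 1e-6) {
  stopifnot(inherits(curve, "lactate_curve"))
  check_positive(target, "target")
  lo <- curve$fit_domain[1]
  hi <- curve$fit_domain[2] + step_width
  grid <- seq(lo, hi, length.out = 4001)
  f <- predict(curve, grid) - target
  rising <- which(f[-length(f)] <= 0 & f[-1] > 0)
  if (length(rising) == 0) {
    # crossing exactly at the left edge
    if (abs(f[1]) < tol) {
      rising <- integer(0)
      root <- lo
    } else {
      stop(sprintf(
        "target never reached: lactate %.3g mmol/L has no rising crossing in [%g, %g] W",
        target, lo, hi), call. = FALSE)
    }
  }
  if (length(rising) > 1) {
    warning(sprintf(
      "multiple rising crossings of %.3g mmol/L; using the lowest power",
      target), call. = FALSE)
  }
  if (length(rising) >= 1) {
    i <- rising[1]
    root <- uniroot(function(w) predict(curve, w) - target,
                    lower = grid[i], upper = grid[i + 1], tol = tol)$root
  }
  tibble::tibble(
    target_lactate = target,
    power_w = root,
    vo2_ml_min = if (is.null(vo2_fit)) NA_real_ else vo2_fit(root),
    hr_bpm = if (is.null(hr_fit)) NA_real_ else hr_fit(root),
    extrapolated = root > curve$fit_domain[2] | root < curve$fit_domain[1]
  )
}

#' Linear fit of a response against power over submaximal steps
#'
#' VO2 (and HR) rise linearly with power below maximal oxygen uptake; steps
#' where VO2 has plateaued are excluded so the fit stays on the linear
#' portion. Returns a function of power.
#'
#' @param powers Step powers, watts.
#' @param response Response values (e.g. `vo2_ml_min`).
#' @param submaximal Logical mask of steps to use; defaults to all.
#' @return Function mapping power to the fitted response.
#' @export
submaximal_linear_fit <- function(powers, response,
                                  submaximal = rep(TRUE, length(powers))) {
  keep <- submaximal & !is.na(response)
  if (sum(keep) < 2) keep <- !is.na(response)
  if (sum(keep) < 2) {
    stop("submaximal_linear_fit: need >= 2 non-missing points",
         call. = FALSE)
  }
  fit <- lm(response[keep] ~ powers[keep])
  b <- unname(coef(fit))
  function(power) b[1] + b[2] * power
}

#' Criteria block for maximal-test outcomes
#'
#' @param plateau_tolerance VO2 window (mL/min) within which a lower power is
#'   considered to already elicit VO2max. Default 150.
#' @param rer_min Attainment flag: maximal RER at or above this. Default 1.10.
#' @param hr_fraction Attainment flag: HRmax at or above this fraction of the
#'   age-predicted maximum (220 - age). Default 0.95.
#' @param lactate_min Attainment flag: end-test lactate at or above this,
#'   mmol/L. Default 8.
#' @return A named list.
#' @export
vo2max_criteria <- function(plateau_tolerance = 150, rer_min = 1.10,
                            hr_fraction = 0.95, lactate_min = 8) {
  list(plateau_tolerance = plateau_tolerance, rer_min = rer_min,
       hr_fraction = hr_fraction, lactate_min = lactate_min)
}

#' Maximal-test outcomes for one subject
#'
#' Extracts VO2max (highest per-step VO2), Wmax (highest power completed),
#' WVO2max (lowest power whose VO2 lies within `plateau_tolerance` of
#' VO2max), HRmax and end-test lactate, plus attainment flags (VO2 plateau,
#' RER, heart rate vs age-predicted maximum, lactate). Flags are reported,
#' never enforced: no subject is dropped silently.
#'
#' @param steps One subject's steps: `power_w`, `vo2_ml_min`, `vco2_ml_min`,
#'   `lactate_mmol_l`, optionally `hr_bpm`.
#' @param mass Body mass, kg.
#' @param age Age in years (for the HR criterion); optional.
#' @param criteria A [vo2max_criteria()] list.
#' @return One-row tibble of maxima and logical attainment flags.
#' @export
max_metrics <- function(steps, mass, age = NA,
                        criteria = vo2max_criteria()) {
  steps <- as.data.frame(steps)
  if (nrow(steps) == 0) {
    stop("max_metrics: empty incremental test", call. = FALSE)
  }
  check_positive(mass, "mass")
  vo2max <- max(steps$vo2_ml_min)
  w_max <- max(steps$power_w)
  near_max <- steps$vo2_ml_min >= vo2max - criteria$plateau_tolerance
  w_vo2max <- min(steps$power_w[near_max])
  plateau_flag <- w_vo2max < w_max
  rer_max <- max(steps$vco2_ml_min / steps$vo2_ml_min)
  hr_max <- if ("hr_bpm" %in% names(steps)) {
    suppressWarnings(max(steps$hr_bpm, na.rm = TRUE))
  } else {
    NA_real_
  }
  if (!is.finite(hr_max)) hr_max <- NA_real_
  lactate_max <- max(steps$lactate_mmol_l)
  tibble::tibble(
    vo2max_l_min = vo2max / 1000,
    vo2max_ml_min_kg = vo2max / mass,
    w_vo2max = w_vo2max,
    w_max = w_max,
    hr_max = hr_max,
    lactate_max = lactate_max,
    rer_max = rer_max,
    flag_plateau = plateau_flag,
    flag_rer = rer_max >= criteria$rer_min,
    flag_hr = if (is.na(hr_max) || is.na(age)) NA else
      hr_max >= criteria$hr_fraction * (220 - age),
    flag_lactate = lactate_max >= criteria$lactate_min
  )
}
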