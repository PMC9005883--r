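#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-zero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  check_number(x, "x")
  check_number(y, "y")
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("pearson_cor: need n >= 3 observations", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("pearson_cor: undefined correlation (zero variance)", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone after sorting and capped at 1.
#'
#' @param pvalues Raw p-values in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  check_probability(pvalues, "pvalues")
  p.adjust(pvalues, method = "BH")
}

#' Mixed-model test of the speed effect on ECR
#'
#' Fits a random-intercept linear mixed model of per-kg ECR on the step speed
#' treated as a categorical factor (each step of the protocol is one level),
#' with subject as the random effect, by REML. Reports the overall
#' speed-effect F-test and all pairwise step contrasts (Wald t-tests on the
#' fixed-effect estimates) with [bh_fdr()]-adjusted p-values. With a single
#' subject a plain OLS fit is used instead, with a warning.
#'
#' @param data Long table with columns named by `ecr_col`, `speed_col`,
#'   `subject_col`.
#' @param ecr_col,speed_col,subject_col Column names. Defaults
#'   `"ecr_per_kg"`, `"speed_ms"`, `"subject_id"`.
#' @return List with `speed_p` (overall test), `contrasts` (tibble:
#'   `level_a`, `level_b`, `estimate`, `se`, `p`, `q`), `model`, and
#'   `random_intercept_sd`.
#' @export
lme_speed_effect <- function(data, ecr_col = "ecr_per_kg",
                             speed_col = "speed_ms",
                             subject_col = "subject_id") {
  df <- data.frame(
    ecr = data[[ecr_col]],
    speed = factor(round(data[[speed_col]], 6)),
    subject = factor(data[[subject_col]])
  )
  df <- df[stats::complete.cases(df), ]
  if (nlevels(df$speed) < 2) {
    stop("lme_speed_effect: need >= 2 speed levels", call. = FALSE)
  }
  single_subject <- nlevels(df$subject) < 2
  if (single_subject) {
    warning(paste("single subject: falling back to ordinary least squares;",
                  "repeated-measures structure cannot be estimated"),
            call. = FALSE)
    fit <- lm(ecr ~ speed, data = df)
    an <- anova(fit)
    speed_p <- an[["Pr(>F)"]][1]
    fe <- coef(fit)
    vc <- vcov(fit)
    dfree <- fit$df.residual
    ri_sd <- NA_real_
  } else {
    fit <- nlme::lme(ecr ~ speed, random = ~ 1 | subject, data = df,
                     method = "REML", na.action = stats::na.omit)
    an <- anova(fit)
    speed_p <- an[["p-value"]][rownames(an) == "speed"]
    fe <- nlme::fixef(fit)
    vc <- vcov(fit)
    dfree <- fit$fixDF$terms[["speed"]]
    vcmp <- nlme::VarCorr(fit)
    ri_sd <- suppressWarnings(as.numeric(vcmp["(Intercept)", "StdDev"]))
  }

  levels_ <- levels(df$speed)
  k <- length(levels_)
  # cell means: reference level is the intercept, others intercept + effect
  combo <- utils::combn(k, 2)
  contrast_row <- function(i, j) {
    # difference (level j) - (level i) in fixed-effect parameterisation
    ci <- numeric(length(fe))
    if (i > 1) ci[i] <- -1
    if (j > 1) ci[j] <- ci[j] + 1
    est <- sum(ci * fe)
    se <- sqrt(drop(t(ci) %*% vc %*% ci))
    tval <- est / se
    p <- 2 * pt(-abs(tval), df = dfree)
    c(est = est, se = se, p = p)
  }
  res <- apply(combo, 2, function(ij) contrast_row(ij[1], ij[2]))
  contrasts <- tibble::tibble(
    level_a = levels_[combo[1, ]],
    level_b = levels_[combo[2, ]],
    estimate = res["est", ],
    se = res["se", ],
    p = res["p", ],
    q = bh_fdr(res["p", ])
  )
  list(speed_p = speed_p, contrasts = contrasts, model = fit,
       random_intercept_sd = ri_sd)
}

#' Two-segment (broken-stick) fit of ECR against speed
#'
#' Continuous piecewise-linear least squares with the breakpoint restricted
#' to the observed step speeds (the protocol's sampling resolution): for each
#' interior candidate speed c the model \eqn{y = a + b_1 x + b_2 (x - c)_+}
#' is fitted and the candidate with minimal residual sum of squares wins;
#' ties are broken toward the largest speed. A plateau is declared when the
#' upper slope falls below `plateau_slope_max` times the lower slope.
#'
#' @param speeds Speeds, m/s (>= 5 points over >= 4 distinct speeds).
#' @param ecr Per-kg ECR values, mLO2/kg/m.
#' @param plateau_slope_max Plateau threshold as a fraction of the lower
#'   slope. Default 0.25.
#' @return A `breakpoint_fit`: `breakpoint_speed`, `slope_below`,
#'   `slope_above`, `intercept`, `rss`, `rss_single_line`, `plateau`,
#'   `n_points`.
#' @export
breakpoint_fit <- function(speeds, ecr, plateau_slope_max = 0.25) {
  check_number(speeds, "speeds")
  check_number(ecr, "ecr")
  if (length(speeds) != length(ecr)) {
    stop("`speeds` and `ecr` must have equal length", call. = FALSE)
  }
  if (length(speeds) < 5 || length(unique(speeds)) < 4) {
    stop("breakpoint_fit: need >= 5 points over >= 4 distinct speeds",
         call. = FALSE)
  }
  ux <- sort(unique(speeds))
  candidates <- ux[-c(1, length(ux))]
  single <- lm(ecr ~ speeds)
  rss_single <- sum(single$residuals^2)
  # tie tolerance on the scale of the data, not of the (possibly zero) RSS
  tie_eps <- 1e-9 * max(sum((ecr - mean(ecr))^2), .Machine$double.xmin)
  best <- NULL
  for (c0 in candidates) {
    hinge <- pmax(speeds - c0, 0)
    fit <- lm(ecr ~ speeds + hinge)
    rss <- sum(fit$residuals^2)
    # candidates are scanned in increasing order; a later candidate whose
    # RSS ties within tolerance wins, so exact ties resolve to the largest
    # speed
    if (is.null(best) || rss < best$rss - tie_eps ||
        abs(rss - best$rss) <= tie_eps) {
      b <- coef(fit)
      best <- list(c0 = c0, rss = rss,
                   intercept = unname(b[1]),
                   slope_below = unname(b[2]),
                   slope_above = unname(b[2] + b[3]))
    }
  }
  plateau <- is.finite(best$slope_below) && best$slope_below > 0 &&
    best$slope_above < plateau_slope_max * best$slope_below
  structure(
    list(breakpoint_speed = best$c0,
         slope_below = best$slope_below,
         slope_above = best$slope_above,
         intercept = best$intercept,
         rss = best$rss,
         rss_single_line = rss_single,
         plateau = plateau,
         n_points = length(speeds)),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<breakpoint_fit> breakpoint %.3f m/s; slopes %.4f -> %.4f ",
           "(mLO2/kg/m per m/s); plateau: %s; n = %d\n"),
    x$breakpoint_speed, x$slope_below, x$slope_above,
    ifelse(x$plateau, "yes", "no"), x$n_points))
  invisible(x)
}

#' Mean-and-SD summary of cohort quantities
#'
#' @param data Data frame of per-subject quantities (numeric columns).
#' @param quantities Columns to summarise; defaults to all numeric columns.
#' @return Tibble with `quantity`, `mean`, `sd` (NA for n = 1), `n`.
#' @export
summary_table <- function(data, quantities = NULL) {
  data <- as.data.frame(data)
  if (is.null(quantities)) {
    quantities <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  rows <- lapply(quantities, function(q) {
    v <- data[[q]]
    v <- v[!is.na(v)]
    tibble::tibble(
      quantity = q,
      mean = if (length(v) > 0) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else NA_real_,
      n = length(v)
    )
  })
  dplyr::bind_rows(rows)
}
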