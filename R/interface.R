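#' Analysis configuration
#'
#' All tunable constants of the analysis pipeline, each with its documented
#' default: the ergometer drag constant (2.8), the lactate oxygen equivalent
#' (3.3 mLO2/kg per mmol/L), the assumed resting lactate used for the first
#' step's accumulation (1.0 mmol/L), whether net lactate clearance is floored
#' at zero in the ECR numerator (yes), whether the sampling rest counts in
#' the accumulation time base (no: the rate is a work rate), the lactate
#' polynomial degree (3), the plateau slope ratio (0.25), the VO2max
#' criteria block, and the FDR level.
#'
#' @param drag_constant Watts at 1 m/s in the cube-law drag model.
#' @param lactate_o2_equivalent mLO2 per kg per mmol/L.
#' @param baseline_lactate Resting lactate, mmol/L.
#' @param lactate_floor Floor negative lactate accumulation at zero?
#' @param include_rest_in_dt Include the sampling rest in the lactate-rate
#'   time base?
#' @param polynomial_degree Lactate-curve degree (2-4).
#' @param plateau_slope_max Plateau declared when the upper slope is below
#'   this fraction of the lower slope.
#' @param pooling_min_n Minimum number of subjects that must have completed
#'   a step for its cohort mean to enter the pooled ECR-vs-speed breakpoint
#'   fit (a "cohort mean" over one or two finishers is not one). Default 3.
#' @param vo2max_criteria A [vo2max_criteria()] block.
#' @param fdr_alpha Significance level applied to FDR-adjusted p-values.
#' @param seed Optional seed recorded for provenance.
#' @return An `ecr_config` list.
#' @export
analysis_config <- function(drag_constant = 2.8,
                            lactate_o2_equivalent = 3.3,
                            baseline_lactate = 1.0,
                            lactate_floor = TRUE,
                            include_rest_in_dt = FALSE,
                            polynomial_degree = 3,
                            plateau_slope_max = 0.25,
                            pooling_min_n = 3,
                            vo2max_criteria = rowergetics::vo2max_criteria(),
                            fdr_alpha = 0.05,
                            seed = NULL) {
  check_positive(drag_constant, "drag_constant")
  check_positive(lactate_o2_equivalent, "lactate_o2_equivalent")
  check_non_negative(baseline_lactate, "baseline_lactate")
  if (!polynomial_degree %in% 2:4) {
    stop("`polynomial_degree` must be 2, 3 or 4", call. = FALSE)
  }
  check_positive(plateau_slope_max, "plateau_slope_max")
  check_probability(fdr_alpha, "fdr_alpha")
  structure(
    list(drag_constant = drag_constant,
         lactate_o2_equivalent = lactate_o2_equivalent,
         baseline_lactate = baseline_lactate,
         lactate_floor = isTRUE(lactate_floor),
         include_rest_in_dt = isTRUE(include_rest_in_dt),
         polynomial_degree = polynomial_degree,
         plateau_slope_max = plateau_slope_max,
         pooling_min_n = pooling_min_n,
         vo2max_criteria = vo2max_criteria,
         fdr_alpha = fdr_alpha,
         seed = seed),
    class = "ecr_config"
  )
}

#' Read an analysis or generator configuration file
#'
#' YAML or JSON (by extension); unknown keys are rejected. Values not present
#' keep their documented defaults.
#'
#' @param path Config file path.
#' @param type `"analysis"` or `"generator"`.
#' @return An `ecr_config` or `generator_config`.
#' @export
read_config <- function(path, type = c("analysis", "generator")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  builder <- if (type == "analysis") analysis_config else generator_config
  known <- names(formals(builder))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(builder, vals)
}

#' Read a cohort from CSV files
#'
#' Validates the on-disk schema (`steps.csv`: subject_id, step_index,
#' power_w, work_s, vo2_ml_min, vco2_ml_min, lactate_mmol_l, optional
#' rest_s / hr_bpm; `subjects.csv`: subject_id, mass_kg, optional height_m,
#' age_yr, time_2000m_s, speed_2000m_ms). Extra columns are preserved.
#' Duplicate (subject, step) rows, non-monotone powers and malformed
#' numerics are fatal; subjects with fewer than two steps are dropped with a
#' named warning.
#'
#' @param steps_path,subjects_path CSV paths. Lines starting `#` (provenance
#'   headers) are skipped.
#' @return A `rower_cohort` list: `subjects`, `steps`.
#' @export
read_cohort <- function(steps_path, subjects_path) {
  for (p in c(steps_path, subjects_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  steps <- tibble::as_tibble(
    read.csv(steps_path, comment.char = "#", stringsAsFactors = FALSE))
  subjects <- tibble::as_tibble(
    read.csv(subjects_path, comment.char = "#", stringsAsFactors = FALSE))

  need_steps <- c("subject_id", "step_index", "power_w", "work_s",
                  "vo2_ml_min", "vco2_ml_min", "lactate_mmol_l")
  miss <- setdiff(need_steps, names(steps))
  if (length(miss) > 0) {
    stop("steps file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(c("subject_id", "mass_kg"), names(subjects))
  if (length(miss) > 0) {
    stop("subjects file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(need_steps, "subject_id")
  for (cc in numeric_cols) {
    if (!is.numeric(steps[[cc]])) {
      stop(sprintf("steps column `%s` contains malformed numeric values", cc),
           call. = FALSE)
    }
  }
  key <- paste(steps$subject_id, steps$step_index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated (subject_id, step_index) row: (",
         sub(" ", ", ", d), ")", call. = FALSE)
  }
  for (sid in unique(steps$subject_id)) {
    s <- steps[steps$subject_id == sid, ]
    s <- s[order(s$step_index), ]
    if (is.unsorted(s$power_w, strictly = TRUE)) {
      stop("non-monotone step powers for subject ", sid, call. = FALSE)
    }
  }
  counts <- table(steps$subject_id)
  thin <- names(counts)[counts < 2]
  if (length(thin) > 0) {
    warning("dropping subject(s) with fewer than 2 steps: ",
            paste(thin, collapse = ", "), call. = FALSE)
    steps <- steps[!steps$subject_id %in% thin, ]
    subjects <- subjects[!subjects$subject_id %in% thin, ]
  }
  orphans <- setdiff(unique(steps$subject_id), subjects$subject_id)
  if (length(orphans) > 0) {
    stop("steps reference unknown subject(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  structure(list(subjects = subjects, steps = steps),
            class = "rower_cohort")
}

#' @export
print.rower_cohort <- function(x, ...) {
  cat(sprintf("<rower_cohort> %d subjects, %d steps%s\n",
              nrow(x$subjects), nrow(x$steps),
              if ("time_2000m_s" %in% names(x$subjects))
                ", with 2,000 m performances" else ""))
  invisible(x)
}

#' Run the full energetic analysis on a cohort
#'
#' Per subject: the ECR profile, the polynomial lactate curve with 2 and
#' 4 mmol/L threshold interpolation (VO2/HR at threshold from submaximal
#' linear fits), and the maximal-test outcomes. Cohort level: the Table-style
#' mean (SD) summary, the correlation battery (per-step ECR vs 2,000 m speed;
#' fat fraction, lactate, RER vs ECR and vs performance at 300/350/400 W;
#' anthropometry and maximal aerobic indices vs performance), the
#' mixed-model speed effect, and the two-segment breakpoint fit on pooled
#' per-step ECR means. Thresholds a subject never reaches are reported as NA
#' ("not reached"), never dropped silently.
#'
#' @param cohort A `rower_cohort` from [read_cohort()] or
#'   [simulate_study()].
#' @param config An [analysis_config()].
#' @return An `ecr_results` list: `step_metrics`, `thresholds`, `summary`,
#'   `correlations`, `breakpoint`, `lme`, `config`.
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "rower_cohort") ||
              (is.list(cohort) && all(c("subjects", "steps") %in%
                                        names(cohort))))
  subjects <- cohort$subjects
  steps <- cohort$steps

  per_subject <- lapply(subjects$subject_id, function(sid) {
    s <- steps[steps$subject_id == sid, ]
    s <- s[order(s$step_index), ]
    mass <- subjects$mass_kg[subjects$subject_id == sid]
    metrics <- ecr_profile(s, mass, config)

    mm <- max_metrics(s, mass,
                      age = if ("age_yr" %in% names(subjects))
                        subjects$age_yr[subjects$subject_id == sid]
                      else NA,
                      criteria = config$vo2max_criteria)
    submax <- s$power_w < mm$w_vo2max
    vo2_fit <- submaximal_linear_fit(s$power_w, s$vo2_ml_min, submax)
    hr_fit <- if ("hr_bpm" %in% names(s)) {
      submaximal_linear_fit(s$power_w, s$hr_bpm, submax)
    } else {
      NULL
    }
    degree <- min(config$polynomial_degree, nrow(s) - 1)
    thr <- lapply(c(2, 4), function(tgt) {
      tryCatch({
        curve <- fit_lactate_curve(s$power_w, s$lactate_mmol_l, degree)
        interpolate_threshold(curve, tgt, vo2_fit, hr_fit,
                              step_width = if (nrow(s) > 1)
                                min(diff(s$power_w)) else 50)
      }, error = function(e) {
        tibble::tibble(target_lactate = tgt, power_w = NA_real_,
                       vo2_ml_min = NA_real_, hr_bpm = NA_real_,
                       extrapolated = NA)
      })
    })
    thresholds <- tibble::tibble(
      subject_id = sid,
      w_blc2 = thr[[1]]$power_w,
      w_blc4 = thr[[2]]$power_w,
      vo2_blc2_l_min = thr[[1]]$vo2_ml_min / 1000,
      vo2_blc4_l_min = thr[[2]]$vo2_ml_min / 1000,
      blc2_extrapolated = thr[[1]]$extrapolated,
      blc4_extrapolated = thr[[2]]$extrapolated,
      ecr_max = subject_ecr_max(metrics)
    )
    thresholds <- dplyr::bind_cols(thresholds, mm)
    list(metrics = metrics, thresholds = thresholds)
  })

  step_metrics <- dplyr::bind_rows(lapply(per_subject, `[[`, "metrics"))
  thresholds <- dplyr::bind_rows(lapply(per_subject, `[[`, "thresholds"))

  summary_df <- build_summary(subjects, thresholds)
  correlations <- build_correlations(step_metrics, thresholds, subjects)

  pooled <- dplyr::summarise(
    dplyr::group_by(step_metrics, .data$power_w),
    speed_ms = mean(.data$speed_ms),
    ecr_per_kg = mean(.data$ecr_per_kg),
    n = dplyr::n(), .groups = "drop")
  pooled_bp <- pooled[pooled$n >= (config$pooling_min_n %||% 3), ]
  bp <- if (nrow(pooled_bp) >= 5) {
    breakpoint_fit(pooled_bp$speed_ms, pooled_bp$ecr_per_kg,
                   plateau_slope_max = config$plateau_slope_max)
  } else {
    NULL
  }
  lme_res <- if (length(unique(step_metrics$subject_id)) >= 2) {
    lme_speed_effect(step_metrics)
  } else {
    NULL
  }

  structure(
    list(step_metrics = step_metrics, thresholds = thresholds,
         summary = summary_df, correlations = correlations,
         breakpoint = bp, lme = lme_res, config = config,
         pooled = pooled),
    class = "ecr_results"
  )
}

build_summary <- function(subjects, thresholds) {
  df <- dplyr::left_join(subjects, thresholds, by = "subject_id")
  cols <- c(age_yr = "age_yr", height_m = "height_m", mass_kg = "mass_kg",
            lactate_max_mmol_l = "lactate_max",
            ecr_max_mlo2_kg_m = "ecr_max",
            vo2max_l_min = "vo2max_l_min",
            vo2max_ml_min_kg = "vo2max_ml_min_kg",
            vo2_blc2_l_min = "vo2_blc2_l_min",
            vo2_blc4_l_min = "vo2_blc4_l_min",
            w_vo2max_w = "w_vo2max", w_blc2_w = "w_blc2",
            w_blc4_w = "w_blc4", w_max_w = "w_max", hr_max_bpm = "hr_max")
  present <- cols[cols %in% names(df)]
  out <- summary_table(df, unname(present))
  out$quantity <- names(present)[match(out$quantity, present)]
  if ("time_2000m_s" %in% names(df)) {
    perf <- summary_table(
      data.frame(time_2000m_min = df$time_2000m_s / 60,
                 speed_2000m_ms = 2000 / df$time_2000m_s))
    out <- dplyr::bind_rows(out, perf)
  }
  out
}

build_correlations <- function(step_metrics, thresholds, subjects) {
  if (!"time_2000m_s" %in% names(subjects)) {
    return(tibble::tibble(label = character(), n = integer(),
                          r = numeric(), p = numeric(), q = numeric()))
  }
  perf <- tibble::tibble(
    subject_id = subjects$subject_id,
    time_2000m_s = subjects$time_2000m_s,
    speed_2000m_ms = 2000 / subjects$time_2000m_s
  )
  rows <- list()
  add <- function(label, df, xcol, ycol) {
    df <- df[stats::complete.cases(df[c(xcol, ycol)]), ]
    if (nrow(df) >= 3 && sd(df[[xcol]]) > 0 && sd(df[[ycol]]) > 0) {
      ct <- pearson_cor(df[[xcol]], df[[ycol]])
      rows[[length(rows) + 1]] <<- tibble::tibble(
        label = label, n = ct$n, r = ct$r, p = ct$p)
    }
  }
  # ECR at each step power vs 2,000 m mean speed
  for (w in sort(unique(step_metrics$power_w))) {
    at_w <- dplyr::inner_join(
      step_metrics[step_metrics$power_w == w, ], perf, by = "subject_id")
    add(sprintf("ecr_%dW_vs_speed2000", w), at_w, "ecr_per_kg",
        "speed_2000m_ms")
  }
  # substrate / lactate / RER battery at 300, 350, 400 W
  for (w in intersect(c(300, 350, 400), unique(step_metrics$power_w))) {
    at_w <- dplyr::inner_join(
      step_metrics[step_metrics$power_w == w, ], perf, by = "subject_id")
    add(sprintf("fat_fraction_%dW_vs_ecr_%dW", w, w), at_w,
        "fat_fraction", "ecr_per_kg")
    add(sprintf("fat_fraction_%dW_vs_time2000", w), at_w,
        "fat_fraction", "time_2000m_s")
    add(sprintf("lactate_%dW_vs_ecr_%dW", w, w), at_w,
        "lactate_mmol_l", "ecr_per_kg")
    add(sprintf("lactate_%dW_vs_fat_fraction_%dW", w, w), at_w,
        "lactate_mmol_l", "fat_fraction")
    add(sprintf("rer_%dW_vs_time2000", w), at_w, "rer", "time_2000m_s")
  }
  # anthropometry and maximal aerobic indices vs performance
  anth <- subjects
  anth$speed_2000m_ms <- 2000 / anth$time_2000m_s
  anth <- dplyr::left_join(
    anth[setdiff(names(anth), c("vo2max_l_min", "w_vo2max"))],
    thresholds[c("subject_id", "vo2max_l_min", "w_vo2max")],
    by = "subject_id")
  add("mass_vs_speed2000", anth, "mass_kg", "speed_2000m_ms")
  if ("height_m" %in% names(anth)) {
    add("height_vs_speed2000", anth, "height_m", "speed_2000m_ms")
  }
  add("vo2max_vs_speed2000", anth, "vo2max_l_min", "speed_2000m_ms")
  add("w_vo2max_vs_speed2000", anth, "w_vo2max", "speed_2000m_ms")

  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$q <- bh_fdr(out$p)
  out
}

#' @export
print.ecr_results <- function(x, ...) {
  cat(sprintf("<ecr_results> %d subjects, %d subject-steps\n",
              nrow(x$thresholds), nrow(x$step_metrics)))
  if (!is.null(x$breakpoint)) print(x$breakpoint)
  if (!is.null(x$lme)) {
    cat(sprintf("  mixed-model speed effect: p = %.3g\n", x$lme$speed_p))
  }
  invisible(x)
}

provenance_header <- function(config) {
  sprintf("# rowergetics %s | config %s | %s",
          as.character(packageVersion("rowergetics")),
          substr(rlang_hash(config), 1, 12),
          format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# stable config digest without extra dependencies
rlang_hash <- function(x) {
  txt <- paste(deparse(x[sort(names(unclass(x)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt)) %% 97) +
            nchar(txt))
}

write_csv_prov <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  write.csv(df, con, row.names = FALSE)
}

#' Write pipeline results to a directory
#'
#' Emits `step_metrics.csv`, `thresholds.csv`, `summary.csv`,
#' `correlations.csv` and `breakpoint.json`. CSVs carry a `#` provenance
#' header (package version, config digest, timestamp) that the package's own
#' readers skip; missing values ("not reached" thresholds) serialize as empty
#' fields.
#'
#' @param results An `ecr_results` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "ecr_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- results$config
  write_csv_prov(results$step_metrics, file.path(dir, "step_metrics.csv"),
                 cfg)
  write_csv_prov(results$thresholds, file.path(dir, "thresholds.csv"), cfg)
  write_csv_prov(results$summary, file.path(dir, "summary.csv"), cfg)
  write_csv_prov(results$correlations, file.path(dir, "correlations.csv"),
                 cfg)
  bp <- results$breakpoint
  payload <- if (is.null(bp)) {
    list(available = FALSE)
  } else {
    c(unclass(bp), list(available = TRUE,
                        lme_speed_p = results$lme$speed_p %||% NA))
  }
  jsonlite::write_json(payload, file.path(dir, "breakpoint.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a simulated study to CSV files
#'
#' Emits `subjects.csv`, `steps.csv` and `truth.csv` (the latent profiles)
#' in the schemas [read_cohort()] consumes.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  write.csv(study$steps, file.path(dir, "steps.csv"), row.names = FALSE)
  write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' ECR-vs-speed figure
#'
#' Pooled per-step means with per-subject trajectories and, optionally, the
#' fitted two-segment model. Requires ggplot2.
#'
#' @param step_metrics The `step_metrics` table of an `ecr_results`.
#' @param breakpoint Optional `breakpoint_fit` to overlay.
#' @return A ggplot object.
#' @export
plot_ecr_speed <- function(step_metrics, breakpoint = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ecr_speed requires the ggplot2 package", call. = FALSE)
  }
  p <- ggplot2::ggplot(step_metrics,
                       ggplot2::aes(x = .data$speed_ms,
                                    y = .data$ecr_per_kg)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.25) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 0.8) +
    ggplot2::labs(x = "Speed (m/s)", y = "ECR (mLO2/kg/m)")
  if (!is.null(breakpoint)) {
    p <- p + ggplot2::geom_vline(xintercept = breakpoint$breakpoint_speed,
                                 linetype = "dashed")
  }
  p
}

cli_usage <- function() {
  paste(
    "usage: rowergetics-cli <simulate|analyze|report> [options]",
    "  simulate --out DIR [--seed INT] [--n INT] [--config PATH]",
    "  analyze  --out DIR [--config PATH]   (reads DIR/steps.csv, DIR/subjects.csv)",
    "  report   --out DIR                    (reads DIR/summary.csv ...)",
    "options: --log-level quiet|info",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    key <- substring(a, 3)
    if (!key %in% c("out", "seed", "n", "config", "log-level")) {
      stop("unknown flag: --", key, call. = FALSE)
    }
    if (i + 1 > length(args)) {
      stop("flag --", key, " needs a value", call. = FALSE)
    }
    flags[[key]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic study to `--out`), `analyze`
#' (run the pipeline on `--out`'s `steps.csv`/`subjects.csv` and write the
#' result files there), `report` (print a mean (SD) summary). Returns the
#' exit code: 0 success, 1 usage or validation failure, 2 internal error. A
#' thin Rscript wrapper lives at `system.file("scripts", "rowergetics-cli",
#' package = "rowergetics")`.
#'
#' @param args Character vector of CLI arguments (defaults to the process
#'   arguments).
#' @return Integer exit code, invisibly.
#' @export
ecr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  quiet <- FALSE
  say <- function(...) if (!quiet) cat(..., "\n", sep = "")
  code <- tryCatch({
    if (length(args) == 0 ||
        !args[1] %in% c("simulate", "analyze", "report")) {
      message(cli_usage())
      return(invisible(1L))
    }
    cmd <- args[1]
    flags <- parse_cli_flags(args[-1])
    quiet <- identical(flags[["log-level"]], "quiet")
    out <- flags[["out"]]
    if (is.null(out)) stop("--out DIR is required", call. = FALSE)

    if (cmd == "simulate") {
      cfg <- if (!is.null(flags$config)) {
        read_config(flags$config, "generator")
      } else {
        generator_config()
      }
      if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
      if (!is.null(flags$n)) cfg$n_subjects <- as.integer(flags$n)
      study <- simulate_study(cfg)
      write_study(study, out)
      say("wrote ", out, "/subjects.csv, steps.csv, truth.csv (n = ",
          cfg$n_subjects, ", seed = ", cfg$seed, ")")
    } else if (cmd == "analyze") {
      cfg <- if (!is.null(flags$config)) {
        read_config(flags$config, "analysis")
      } else {
        analysis_config()
      }
      cohort <- read_cohort(file.path(out, "steps.csv"),
                            file.path(out, "subjects.csv"))
      res <- run_pipeline(cohort, cfg)
      write_results(res, out)
      say("wrote analysis results to ", out)
    } else { # report
      sp <- file.path(out, "summary.csv")
      if (!file.exists(sp)) stop("no summary at ", sp, call. = FALSE)
      s <- read.csv(sp, comment.char = "#")
      cat("Cohort summary - data are presented as mean (SD)\n")
      for (i in seq_len(nrow(s))) {
        cat(sprintf("  %-22s %8.3g (%.3g)   n=%d\n", s$quantity[i],
                    s$mean[i], s$sd[i], s$n[i]))
      }
      bpp <- file.path(out, "breakpoint.json")
      if (file.exists(bpp)) {
        bp <- jsonlite::read_json(bpp)
        if (isTRUE(bp$available)) {
          cat(sprintf("ECR plateau onset: %.2f m/s (slopes %.3f -> %.3f)\n",
                      bp$breakpoint_speed, bp$slope_below, bp$slope_above))
        }
      }
    }
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    # validation/user errors exit 1; unexpected internals exit 2
    if (inherits(e, "simpleError")) 1L else 2L
  })
  invisible(code)
}
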