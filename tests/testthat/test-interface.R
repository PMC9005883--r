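test_that("a well-formed cohort loads cleanly and round-trips", {
  dir <- withr::local_tempdir()
  paths <- tiny_cohort_files(dir)
  cohort <- read_cohort(paths$steps, paths$subjects)
  expect_s3_class(cohort, "rower_cohort")
  expect_equal(nrow(cohort$subjects), 2)
  expect_equal(nrow(cohort$steps), 8)
})

test_that("schema violations are fatal and name the problem", {
  dir <- withr::local_tempdir()
  paths <- tiny_cohort_files(dir)
  steps <- read.csv(paths$steps)
  no_lactate <- steps[setdiff(names(steps), "lactate_mmol_l")]
  write.csv(no_lactate, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "bad.csv"), paths$subjects),
               "lactate_mmol_l")
  dup <- rbind(steps, steps[3, ])
  write.csv(dup, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "dup.csv"), paths$subjects),
               "\\(A, 3\\)")
  swapped <- steps
  swapped$power_w[swapped$subject_id == "A"] <-
    rev(swapped$power_w[swapped$subject_id == "A"])
  write.csv(swapped, file.path(dir, "swap.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "swap.csv"), paths$subjects),
               "non-monotone")
  expect_error(read_cohort(file.path(dir, "nothere.csv"), paths$subjects),
               "nothere")
})

test_that("subjects with fewer than two steps are dropped with a warning", {
  dir <- withr::local_tempdir()
  paths <- tiny_cohort_files(dir)
  steps <- read.csv(paths$steps)
  thin <- steps[!(steps$subject_id == "B" & steps$step_index > 1), ]
  write.csv(thin, file.path(dir, "thin.csv"), row.names = FALSE)
  expect_warning(
    cohort <- read_cohort(file.path(dir, "thin.csv"), paths$subjects),
    "B")
  expect_equal(cohort$subjects$subject_id, "A")
})

test_that("the pipeline produces a complete, schema-stable result bundle", {
  study <- simulate_study(generator_config(seed = 3))
  res <- run_pipeline(study)
  expect_s3_class(res, "ecr_results")
  expect_true(all(c("subject_id", "ecr_per_kg", "fat_fraction", "rer") %in%
                    names(res$step_metrics)))
  expect_equal(nrow(res$thresholds), 21)
  expect_true(all(c("w_blc2", "w_blc4", "ecr_max", "w_max") %in%
                    names(res$thresholds)))
  expect_s3_class(res$breakpoint, "breakpoint_fit")
  expect_lt(res$lme$speed_p, 0.001)
  expect_true(all(res$correlations$q >= res$correlations$p))

  dir <- withr::local_tempdir()
  write_results(res, dir)
  files <- c("step_metrics.csv", "thresholds.csv", "summary.csv",
             "correlations.csv", "breakpoint.json")
  expect_true(all(file.exists(file.path(dir, files))))
  # outputs re-read by the package's own conventions (header skipped)
  again <- read.csv(file.path(dir, "thresholds.csv"), comment.char = "#")
  expect_equal(nrow(again), 21)
  expect_equal(again$ecr_max, res$thresholds$ecr_max, tolerance = 1e-9)
  bp <- jsonlite::read_json(file.path(dir, "breakpoint.json"))
  expect_equal(bp$breakpoint_speed, res$breakpoint$breakpoint_speed,
               tolerance = 1e-9)
})

test_that("unreached thresholds are reported as missing, not dropped", {
  dir <- withr::local_tempdir()
  paths <- tiny_cohort_files(dir)
  steps <- read.csv(paths$steps)
  steps$lactate_mmol_l <- 1 + 0.1 * steps$step_index # never near 4
  write.csv(steps, file.path(dir, "low.csv"), row.names = FALSE)
  cohort <- read_cohort(file.path(dir, "low.csv"), paths$subjects)
  res <- run_pipeline(cohort)
  expect_equal(nrow(res$thresholds), 2)
  expect_true(all(is.na(res$thresholds$w_blc4)))
  dirout <- withr::local_tempdir()
  write_results(res, dirout)
  txt <- readLines(file.path(dirout, "thresholds.csv"))
  expect_false(any(grepl("-999|NaN", txt)))
})

test_that("pipeline is deterministic given identical inputs and config", {
  study <- simulate_study(generator_config(seed = 4, n_subjects = 8))
  r1 <- run_pipeline(study)
  r2 <- run_pipeline(study)
  r1$config <- r2$config <- NULL
  expect_equal(r1[c("step_metrics", "thresholds", "summary",
                    "correlations")],
               r2[c("step_metrics", "thresholds", "summary",
                    "correlations")])
})

test_that("configs round-trip through YAML and JSON", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(drag_constant = 3.0, polynomial_degree = 4), yml)
  cfg <- read_config(yml, "analysis")
  expect_equal(cfg$drag_constant, 3.0)
  expect_equal(cfg$polynomial_degree, 4)
  expect_equal(cfg$lactate_o2_equivalent, 3.3) # untouched default
  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(n_subjects = 5, seed = 99), jsn,
                       auto_unbox = TRUE)
  gcfg <- read_config(jsn, "generator")
  expect_equal(gcfg$n_subjects, 5)
  expect_equal(gcfg$seed, 99)
  yaml::write_yaml(list(not_a_key = 1), yml)
  expect_error(read_config(yml, "analysis"), "not_a_key")
})

test_that("the CLI simulates, analyzes and reports with proper exit codes", {
  dir <- withr::local_tempdir()
  expect_equal(ecr_cli(c("simulate", "--seed", "7", "--n", "6",
                         "--out", dir, "--log-level", "quiet")), 0L)
  expect_true(file.exists(file.path(dir, "steps.csv")))
  expect_equal(ecr_cli(c("analyze", "--out", dir, "--log-level",
                         "quiet")), 0L)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  out <- capture.output(code <- ecr_cli(c("report", "--out", dir)))
  expect_equal(code, 0L)
  expect_true(any(grepl("mean \\(SD\\)", out)))
  # failures: missing directory, unknown flag, no subcommand
  expect_equal(suppressMessages(
    ecr_cli(c("analyze", "--out", file.path(dir, "missing")))), 1L)
  expect_equal(suppressMessages(ecr_cli(c("simulate", "--bogus", "1"))), 1L)
  expect_equal(suppressMessages(ecr_cli(character(0))), 1L)
})
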