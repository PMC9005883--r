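test_that("pearson correlation matches direct sum computation", {
  expect_equal(pearson_cor(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_cor(1:3, c(3, 2, 1))$r, -1)
  # hand computation: r = 3/sqrt(2*14/3) = 0.9820
  r <- pearson_cor(1:3, c(1, 2, 4))
  expect_equal(round(r$r, 4), 0.9820)
  # random instances against the covariance/variance formula
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    got <- pearson_cor(x, y)
    expect_equal(got$r, direct, tolerance = 1e-12)
    tstat <- direct * sqrt((n - 2) / (1 - direct^2))
    expect_equal(got$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  }
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
  expect_error(pearson_cor(c(1, 1, 1), 1:3), "zero variance")
})

# independent brute-force of the BH step-up rule
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    # q_(i) = min over j >= i of p_(j) * n / j, capped at 1
    js <- i:n
    q[o[i]] <- min(1, min(p[o[js]] * n / js))
  }
  q
}

test_that("BH adjustment equals the brute-force step-up on small sets", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(1.0), 1.0)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  base <- c(0.001, 0.011, 0.04, 0.24, 0.5, 0.93)
  for (k in 1:6) {
    set.seed(k)
    for (rep in 1:20) {
      p <- sample(base, k)
      expect_equal(bh_fdr(p), bh_brute(p))
    }
  }
  set.seed(7)
  p <- runif(25)
  expect_equal(bh_fdr(p), bh_brute(p))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("mixed model finds no speed effect when none exists", {
  # subject offsets only; a whisper of noise keeps the REML fit well-posed
  set.seed(21)
  df <- expand.grid(subject_id = paste0("S", 1:8),
                    speed_ms = c(4, 4.5, 5, 5.4))
  offsets <- setNames(seq(0, 0.05, length.out = 8), paste0("S", 1:8))
  df$ecr_per_kg <- 0.18 + offsets[df$subject_id] + rnorm(nrow(df), sd = 1e-4)
  res <- suppressWarnings(lme_speed_effect(df))
  expect_gt(res$speed_p, 0.05)
  expect_true(all(res$contrasts$q > 0.05))
  # estimated speed-level differences are negligible against the offsets
  expect_lt(max(abs(res$contrasts$estimate)), 0.001)
})

test_that("mixed model recovers subject-offset variance on constructed data", {
  # pure subject intercepts + common speed trend, no residual noise beyond
  # a tiny jitter for estimability
  set.seed(3)
  subjects <- paste0("S", 1:8)
  offsets <- rnorm(8, sd = 0.02)
  df <- expand.grid(subject_id = subjects, speed_ms = c(4, 4.4, 4.8, 5.2))
  df$ecr_per_kg <- 0.15 + 0.02 * df$speed_ms +
    offsets[match(df$subject_id, subjects)] + rnorm(nrow(df), sd = 5e-4)
  res <- lme_speed_effect(df)
  expect_lt(res$speed_p, 1e-6)
  expect_equal(res$random_intercept_sd, sd(offsets), tolerance = 0.25)
  # contrasts estimate the true mean differences between speed levels
  c12 <- res$contrasts[res$contrasts$level_a == "4" &
                         res$contrasts$level_b == "4.4", ]
  expect_equal(c12$estimate, 0.02 * 0.4, tolerance = 0.05)
})

test_that("single-subject input falls back to OLS with a warning", {
  df <- data.frame(subject_id = "S1", speed_ms = rep(c(4, 4.5, 5), each = 3),
                   ecr_per_kg = rep(c(0.16, 0.18, 0.20), each = 3) +
                     rnorm(9, sd = 1e-3))
  expect_warning(res <- lme_speed_effect(df), "single subject")
  expect_lt(res$speed_p, 0.01)
})

test_that("broken-stick fit recovers a noiseless breakpoint exactly", {
  speeds <- c(4.2, 4.5, 4.8, 5.0, 5.2, 5.4, 5.6)
  ecr <- 0.01 + 0.04 * pmin(speeds, 5.2) + 0.0 * pmax(speeds - 5.2, 0)
  fit <- breakpoint_fit(speeds, ecr)
  expect_equal(fit$breakpoint_speed, 5.2)
  expect_equal(fit$slope_below, 0.04, tolerance = 1e-9)
  expect_equal(fit$slope_above, 0, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-20)
  expect_true(fit$plateau)
  # non-zero upper slope, still recovered exactly
  ecr2 <- 0.01 + 0.04 * pmin(speeds, 4.8) + 0.015 * pmax(speeds - 4.8, 0)
  fit2 <- breakpoint_fit(speeds, ecr2)
  expect_equal(fit2$breakpoint_speed, 4.8)
  expect_equal(fit2$slope_above, 0.015, tolerance = 1e-9)
})

test_that("a perfect single line ties and resolves to the largest speed", {
  speeds <- seq(4, 5.6, by = 0.2)
  ecr <- 0.02 + 0.035 * speeds
  fit <- breakpoint_fit(speeds, ecr)
  expect_equal(fit$slope_below, fit$slope_above, tolerance = 1e-7)
  expect_false(fit$plateau)
  # tie broken toward the largest interior candidate
  expect_equal(fit$breakpoint_speed, speeds[length(speeds) - 1])
})

test_that("two-segment RSS never exceeds the single-line RSS", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    speeds <- sort(runif(n, 4, 5.7))
    ecr <- 0.03 * speeds + rnorm(n, sd = 0.01)
    fit <- breakpoint_fit(speeds, ecr)
    expect_lte(fit$rss, fit$rss_single_line + 1e-12)
    expect_gt(fit$breakpoint_speed, min(speeds))
    expect_lt(fit$breakpoint_speed, max(speeds))
  }
  expect_error(breakpoint_fit(c(4, 4.5, 5, 5.5), c(1, 2, 3, 4)), ">= 5")
})

test_that("summary table reports mean and n-1 SD, NA for singletons", {
  s <- summary_table(data.frame(x = c(5, 6, 7)))
  expect_equal(s$mean, 6)
  expect_equal(s$sd, 1)
  one <- summary_table(data.frame(x = 5))
  expect_true(is.na(one$sd))
  expect_equal(one$n, 1)
})
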