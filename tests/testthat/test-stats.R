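test_that("identical phase distributions give F ~ 0, p ~ 1", {
  d <- data.frame(phase = rep(c("pre", "during", "post"), each = 4),
                  value = rep(c(1, 2, 3, 4), 3))
  res <- anova_phases(d)
  expect_lt(res$f_statistic, 1e-20)
  expect_gt(res$p_value, 0.999)
})

test_that("two-group ANOVA reduces to the t test (F = t^2)", {
  set.seed(1)
  d <- data.frame(phase = rep(c("pre", "post"), each = 8), value = rnorm(16))
  res <- anova_phases(d)
  tt <- t.test(value ~ phase, data = d, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("a shifted phase is detected and Tukey flags exactly its two pairs", {
  set.seed(2024)
  hits <- replicate(100, {
    d <- data.frame(phase = rep(c("pre", "during", "post"), each = 20),
                    value = c(rnorm(20), rnorm(20), rnorm(20, mean = 5)))
    res <- anova_phases(d)
    tk <- tidy(res)
    involves_post <- grepl("post", tk$pair)
    res$p_value < 0.001 && all(tk$significant == involves_post)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("ANOVA is invariant to relabeling and constant shifts", {
  set.seed(5)
  d <- data.frame(phase = rep(c("pre", "during", "post"), each = 6),
                  value = rnorm(18))
  f0 <- anova_phases(d)$f_statistic
  d_shift <- transform(d, value = value + 100)
  expect_equal(anova_phases(d_shift)$f_statistic, f0, tolerance = 1e-9)
  d_relab <- transform(d, phase = factor(phase, levels = c("post", "pre", "during")))
  expect_equal(anova_phases(d_relab)$f_statistic, f0, tolerance = 1e-9)
})

test_that("insufficient cells are rejected with a clear message", {
  expect_error(anova_phases(data.frame(phase = c("pre", "post"), value = 1:2)),
               ">= 2 observations")
})

test_that("an exact line is recovered perfectly", {
  d <- data.frame(subject_id = letters[1:10], ga_weeks = c(24:30, 38:40))
  d$value <- 2 * d$ga_weeks
  g <- glance(regress_on_ga(d))
  expect_equal(g$slope, 2, tolerance = 1e-12)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)
  expect_lt(g$p_value, 1e-12)
  expect_error(regress_on_ga(transform(d, ga_weeks = 30)), "distinct gestational")
})

test_that("repeated sessions are pooled per subject unless per_session", {
  d <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 3),
                  ga_weeks = rep(c(24, 27, 30, 39), each = 3),
                  value = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12))
  pooled <- regress_on_ga(d)
  expect_equal(pooled$n, 4)
  sess <- regress_on_ga(d, per_session = TRUE)
  expect_equal(sess$n, 12)
  expect_equal(pooled$slope, sess$slope, tolerance = 1e-9)  # balanced design
})

test_that("permuted gestational ages reject at the nominal 5% rate", {
  set.seed(99)
  n <- 51
  ga <- c(runif(25, 23, 29), runif(22, 29, 34), runif(4, 37, 41))
  value <- rnorm(n, 50, 15)
  d <- data.frame(subject_id = sprintf("s%02d", 1:n), ga_weeks = ga, value = value)
  rate <- mean(replicate(1000, {
    d$ga_weeks <- sample(ga)
    regress_on_ga(d)$p_value < 0.05
  }))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("steeper injected feeding gains give steeper recovered mPSD slopes", {
  slopes <- sapply(c(0, 0.04, 0.08), function(k) {
    params <- sim_params(fs_raw = 16, duration_min = 96,
                         feed_times = list(c(30, 30)),
                         feed_gain_fn = function(ga) pmax(1 + k * (ga - 23), 0.2))
    coh <- simulate_cohort(c(6, 6, 3), params, master_seed = 31,
                           keep_recordings = FALSE)
    f <- cohort_features(coh, egg_options(allow_single_feed = TRUE),
                         features = "mpsd")
    d <- f[f$band == "normo" & f$phase == "during", ]
    glance(regress_on_ga(d, value = "value"))$slope
  })
  expect_true(all(diff(slopes) > 0))
})

test_that("the battery helpers cover every cell and mark unavailable ones", {
  set.seed(12)
  features <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:9),
    phase = factor(phase_levels(), levels = phase_levels()),
    band = factor(band_levels(), levels = band_levels()),
    feature = "pct_time"
  )
  features$ga_weeks <- rep(c(24, 25, 26, 30, 31, 32, 38, 39, 40),
                           each = 9)[seq_len(nrow(features))]
  features$ga_group <- ga_group_of(features$ga_weeks)
  features$value <- rnorm(nrow(features), 50, 10)
  an <- anova_battery(features)
  expect_true(all(an$available))
  expect_equal(nrow(an), 3 * 3 * 3)  # group x band x 3 Tukey pairs
  rg <- regression_battery(features)
  expect_equal(nrow(rg), 9)          # phase x band
  expect_true(all(rg$available))

  # single-group degenerate cohort: ANOVA still works across phases, and a
  # cohort with too few distinct ages marks regressions unavailable
  tiny <- features[features$subject_id %in% c("s01", "s02"), ]
  rg2 <- regression_battery(tiny)
  expect_true(all(!rg2$available))
})
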