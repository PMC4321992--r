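test_that("VAS scaling maps the reference mean to 100", {
  df <- tibble::tibble(
    subject_id = 1L, block = 4L, stimulus_level = "high",
    cue = c("red", "red", "green"),
    vas_raw = c(50, 50, 35)
  )
  out <- scale_vas(df)
  expect_equal(sort(out$vas_scaled), c(70, 100, 100))

  flat <- tibble::tibble(subject_id = 1L, block = 1L,
                         stimulus_level = c("high", "low"),
                         cue = c("red", "green"), vas_raw = c(40, 40))
  expect_equal(scale_vas(flat)$vas_scaled, c(100, 100))

  zero <- tibble::tibble(subject_id = 7L, block = 2L,
                         stimulus_level = "high", cue = "red", vas_raw = 0)
  expect_error(scale_vas(zero), "subject 7 block 2")
})

test_that("VAS scaling is idempotent", {
  coh <- simulate_cohort(cohort_spec(2, 2, seed = 44))
  once <- scale_vas(coh$ratings)
  again <- once
  again$vas_raw <- once$vas_scaled
  twice <- scale_vas(again)
  expect_equal(twice$vas_scaled, once$vas_scaled, tolerance = 1e-12)
})

test_that("placebo magnitude follows its sign convention", {
  rec <- function(red, green) tibble::tibble(
    stimulus_level = "high",
    cue = rep(c("red", "green"), c(length(red), length(green))),
    vas_raw = c(red, green)
  )
  expect_equal(placebo_magnitude(rec(c(50, 50), 35)), 30)
  expect_equal(placebo_magnitude(rec(50, 50)), 0)
  expect_equal(placebo_magnitude(rec(50, 60)), -20)
  expect_error(placebo_magnitude(rec(numeric(0), 50)), "red")
  expect_error(placebo_magnitude(rec(0, 10)), "zero")
})

test_that("the expectation weight is recovered from rich placebo data", {
  p_true <- subject_params(w = 0.9)
  g <- intensity_grid()
  withr::with_seed(606, {
    green <- oracle_rating_draws(50, 80, "green", p_true, g)
    red <- oracle_rating_draws(50, 80, "red", p_true, g)
  })
  fit <- fit_w(placebo_records(green, red), subject_params(), g)
  expect_lt(abs(fit$results$w_hat - 0.9), 0.1)

  p0 <- subject_params(w = 0)
  withr::with_seed(607, {
    green0 <- oracle_rating_draws(50, 80, "green", p0, g)
    red0 <- oracle_rating_draws(50, 80, "red", p0, g)
  })
  fit0 <- fit_w(placebo_records(green0, red0), subject_params(), g)
  expect_lte(fit0$results$w_hat, 0.15)
})

test_that("fit_w validates its inputs and fits subjects independently", {
  g <- intensity_grid()
  expect_error(fit_w(placebo_records(numeric(0), numeric(0)),
                     subject_params(), g), "placebo")
  only_red <- placebo_records(numeric(0), c(70, 75, 80))
  expect_error(fit_w(only_red, subject_params(), g), "green")

  two <- dplyr::bind_rows(
    placebo_records(c(20, 22, 25, 78), c(78, 80, 82, 79), subject_id = 1L),
    placebo_records(c(76, 80, 84, 79), c(78, 81, 83, 80), subject_id = 2L)
  )
  fit <- fit_w(two, subject_params(), g)
  expect_equal(nrow(tidy(fit)), 2L)
  expect_gt(fit$results$w_hat[1], fit$results$w_hat[2])
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("fitted sigma orders cohorts by their true prior dispersion", {
  g <- intensity_grid()
  fit_at <- function(sig, seed) {
    coh <- simulate_cohort(cohort_spec(8, 1, w = "uniform", sigma_prior = sig,
                                       seed = seed), g)
    glance(fit_sigma(coh$ratings, subject_params(), g))$sigma_mean
  }
  s3 <- fit_at(3, 81)
  s9 <- fit_at(9, 82)
  expect_lt(s3, s9)
})

test_that("degenerate subjects are flagged by fit_sigma, not fatal", {
  const <- tibble::tibble(
    subject_id = 1L, experiment = 1L,
    block = rep(1:3, each = 12),
    trial = rep(1:12, 3),
    cue = rep(rep(c("red", "green"), each = 6), 3),
    stimulus_level = c(rep(rep(c("high", "low"), each = 6), 2),
                       rep("high", 12)),
    stimulus_intensity = 50,
    vas_raw = 50,
    vas_scaled = NA_real_
  )
  out <- tidy(fit_sigma(const, subject_params(), intensity_grid()))
  expect_true(out$degenerate)
  expect_true(is.na(out$sigma_hat))
})

test_that("explained variance matches the declared 1 - r^2 definition", {
  ev <- explained_variance(1:10, 2 * (1:10) + 1)
  expect_equal(ev$r, 1)
  expect_equal(ev$residual_variance_pct, 0)

  # construct vectors with r = 0.84 exactly: residual variance is 29.44
  x <- c(-1, 0, 1)
  r_target <- 0.84
  y <- r_target * x + sqrt(1 - r_target^2) * c(1, -2, 1) / sqrt(6) * sqrt(2)
  ev2 <- explained_variance(x, y)
  expect_equal(ev2$r, 0.84, tolerance = 1e-10)
  expect_equal(ev2$residual_variance_pct, 100 * (1 - 0.84^2),
               tolerance = 1e-8)

  set.seed(9)
  a <- c(3, 1, 4, 1, 5)
  b <- c(2, 7, 1, 8, 2)
  ev3 <- explained_variance(a, b)
  oc <- oracle_pearson(a, b)
  expect_equal(ev3$r, oc$r, tolerance = 1e-10)
  expect_equal(ev3$p_one_tailed, oc$p, tolerance = 1e-10)

  expect_error(explained_variance(1:2, 1:2), "3")
  expect_error(explained_variance(rep(1, 5), 1:5), "constant")
})
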