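test_that("model posteriors are a proper distribution over the model set", {
  g <- intensity_grid()
  pts <- grid_points(g)
  same <- belief(g, dnorm(pts, 50, 10))
  other <- belief(g, dnorm(pts, 60, 10))

  two <- model_posteriors(c(48, 52), list(a = same, b = same))
  expect_equal(two$posterior, c(0.5, 0.5))
  expect_equal(two$bayes_factor, c(1, 1))

  three <- model_posteriors(c(45, 50, 55),
                            list(a = same, b = other,
                                 c = belief(g, dnorm(pts, 40, 15))))
  expect_equal(sum(three$posterior), 1, tolerance = 1e-9)
  expect_equal(three$model[which.max(three$posterior)], "a")
  # the winner's Bayes factor vs runner-up exceeds 1, all others are below
  expect_gt(max(three$bayes_factor), 1)
  expect_true(all(three$bayes_factor[-which.max(three$posterior)] <= 1))
  expect_warning(model_posteriors(c(150), list(a = same, b = other)),
                 "clamped")
})

test_that("two-cluster solutions reproduce forced arithmetic cases", {
  km <- kmeans2(c(0, 0, 10, 10))
  expect_equal(km$centers, c(0, 10))
  expect_equal(km$center_distance, 10)
  expect_equal(km$separation_index, 1)

  km2 <- kmeans2(c(0, 2, 8, 10))
  expect_equal(km2$centers, c(1, 9))
  expect_equal(km2$within_ss, 4)
  expect_equal(km2$total_ss, 68)
  expect_equal(km2$separation_index, 64 / 68)
  expect_equal(km2$assignment, c(1, 1, 2, 2))

  expect_error(kmeans2(rep(3, 5)), "all scores are equal")
  expect_error(kmeans2(5), "two scores")
})

test_that("k-means matches the exhaustive optimal 2-partition", {
  set.seed(321)
  for (rep_i in 1:12) {
    n <- sample(4:12, 1)
    x <- c(rnorm(ceiling(n / 2), 30, 6), rnorm(floor(n / 2), 75, 9))
    km <- kmeans2(x)
    oracle <- oracle_best_2partition(x)
    expect_equal(km$within_ss, oracle$within_ss, tolerance = 1e-8)
    expect_equal(km$centers, sort(oracle$centers), tolerance = 1e-8)
    expect_true(km$separation_index >= 0 && km$separation_index <= 1)
  }
})

test_that("bimodality test favours separated clusters and matches arithmetic", {
  withr::with_seed(55, {
    sep <- c(rnorm(4, 30, 2), rnorm(4, 100, 2))
  })
  bt <- bimodality_test(sep)
  expect_gt(bt$posterior_prob_bimodal, 0.5)
  expect_gt(bt$bayes_factor, 1)

  # arithmetic oracle on a tight unimodal sample
  withr::with_seed(56, {
    uni <- rnorm(8, 50, 1.5)
  })
  bt_u <- suppressWarnings(bimodality_test(uni))
  km <- kmeans2(uni)
  ll_uni <- sum(dnorm(uni, mean(uni), sd(uni), log = TRUE))
  cl <- split(uni, km$assignment)
  pi_k <- vapply(cl, length, numeric(1)) / length(uni)
  mix <- pi_k[1] * dnorm(uni, mean(cl[[1]]), max(sd(cl[[1]]), 0.5)) +
    pi_k[2] * dnorm(uni, mean(cl[[2]]), max(sd(cl[[2]]), 0.5))
  ll_bi <- sum(log(mix))
  expect_equal(bt_u$posterior_prob_bimodal,
               1 / (1 + exp(ll_uni - ll_bi)), tolerance = 1e-9)
  expect_equal(bt_u$bayes_factor, exp(ll_bi - ll_uni), tolerance = 1e-9)
  expect_equal(bt_u$posterior_prob_bimodal,
               bt_u$bayes_factor / (1 + bt_u$bayes_factor), tolerance = 1e-9)

  expect_error(bimodality_test(c(1, 2, 3)), "at least 4")
  expect_warning(bimodality_test(c(10, 10, 10, 50, 50, 50, 50, 10)),
                 "floor")
})

test_that("one-tailed Pearson matches the formula oracle", {
  expect_equal(pearson_one_tailed(1:5, 2 * (1:5) + 1)$r, 1)
  neg <- pearson_one_tailed(1:5, -(1:5))
  expect_equal(neg$r, -1)
  expect_gt(neg$p, 0.5)

  x <- c(2, 9, 4, 7, 1)
  y <- c(3, 8, 6, 9, 2)
  got <- pearson_one_tailed(x, y)
  oc <- oracle_pearson(x, y)
  expect_equal(got$r, oc$r, tolerance = 1e-10)
  expect_equal(got$p, oc$p, tolerance = 1e-10)

  expect_error(pearson_one_tailed(rep(1, 4), 1:4), "constant")
  expect_error(pearson_one_tailed(1:2, 1:2), "n >= 3")
})

test_that("rank-sum P-values match full enumeration", {
  p <- rank_tests(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(p$p, 1 / 20)
  expect_true(p$exact)

  set.seed(88)
  for (i in 1:5) {
    a <- round(rnorm(sample(3:6, 1), 50, 20), 3)
    b <- round(rnorm(sample(3:6, 1), 60, 20), 3)
    for (alt in c("less", "greater")) {
      expect_equal(rank_tests(a, b, alternative = alt)$p,
                   oracle_mann_whitney_p(a, b, alt), tolerance = 1e-12)
    }
  }
})

test_that("signed-rank P-values match sign-pattern enumeration", {
  set.seed(99)
  for (i in 1:5) {
    a <- round(rnorm(6, 50, 10), 3)
    b <- round(a + rnorm(6, -4, 6), 3)
    for (alt in c("less", "greater")) {
      expect_equal(rank_tests(a, b, paired = TRUE, alternative = alt)$p,
                   oracle_signed_rank_p(a, b, alt), tolerance = 1e-12)
    }
  }
  expect_error(rank_tests(c(1, 2), c(1, 2), paired = TRUE), "zero")
  expect_error(rank_tests(c(1, 2), c(1, 2, 3), paired = TRUE), "equal length")
})
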