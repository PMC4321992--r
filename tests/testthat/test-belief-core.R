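# priors ----------------------------------------------------------------------

test_that("prior collapses to uniform at w = 0 and splits evenly at w = 1", {
  g <- intensity_grid(0, 100, 1)
  p <- subject_params(w = 0, sigma_prior = 5)
  pr <- build_prior(p, g)
  expect_equal(pr$mass, rep(1 / 101, 101), tolerance = 1e-12)

  p1 <- subject_params(w = 1, sigma_prior = 5)
  pr1 <- build_prior(p1, g)
  below <- sum(pr1$mass[grid_points(g) < 50])
  expect_equal(below, 0.5, tolerance = 1e-6)
})

test_that("prior mass matches the direct mixture-density oracle", {
  g <- default_grid()
  p <- subject_params(w = 0.9, sigma_prior = 5.7)
  pr <- build_prior(p, g)
  expect_equal(pr$mass,
               oracle_prior_mass(g, 0.9, 20, 80, 5.7, "none"),
               tolerance = 1e-12)
})

test_that("prior rejects invalid parameters", {
  g <- default_grid()
  p <- default_params()
  expect_error(build_prior(p, g, w = 1.2), "\\[0, 1\\]")
  expect_error(build_prior(p, g, w = -0.1), "\\[0, 1\\]")
  expect_error(subject_params(sigma_prior = 0), "positive")
  expect_error(subject_params(s_low = 80, s_high = 20), "anchors")
})

test_that("cue priors select the associated component", {
  g <- default_grid()
  p <- subject_params(w = 1, sigma_prior = 5)

  none <- build_cue_prior("none", p, g)
  expect_identical(none$mass, build_prior(p, g)$mass)

  green <- build_cue_prior("green", p, g)
  expect_equal(grid_points(g)[which.max(green$mass)], 20)
  red <- build_cue_prior("red", p, g)
  expect_equal(grid_points(g)[which.max(red$mass)], 80)

  expect_error(build_cue_prior("blue", p, g), "cue")
})

test_that("green-cue prior window mass matches the density oracle", {
  g <- default_grid()
  p <- subject_params(w = 0.5, sigma_prior = 5)
  green <- build_cue_prior("green", p, g)
  oracle <- oracle_prior_mass(g, 0.5, 20, 80, 5, "green")
  win <- grid_points(g) >= 20 - 10 & grid_points(g) <= 20 + 10
  expect_equal(sum(green$mass[win]), sum(oracle[win]), tolerance = 1e-12)
  expect_equal(green$mass, oracle, tolerance = 1e-12)
})

# likelihood kernel ------------------------------------------------------------

test_that("kernel rows are centred Gaussians that renormalize to one", {
  g <- default_grid()
  k <- likelihood_kernel(g, sd = 20)
  pts <- grid_points(g)
  row50 <- k$rows[pts == 50, ]
  expect_equal(pts[which.max(row50)], 50)
  expect_equal(unname(rowSums(k$rows)), rep(1, length(pts)), tolerance = 1e-9)

  # fine grid: mass ratio at one s.d. from the mean is exp(-1/2)
  gf <- intensity_grid(0, 20, 0.05)
  kf <- likelihood_kernel(gf, sd = 0.75)
  ptsf <- grid_points(gf)
  row <- kf$rows[ptsf == 10, ]
  ratio <- row[ptsf == 10.75] / row[ptsf == 10]
  expect_equal(unname(ratio), exp(-1 / 2), tolerance = 1e-3)

  expect_error(likelihood_kernel(g, sd = 0), "positive")
})

# posterior and decision -------------------------------------------------------

test_that("posterior under a flat prior peaks at the observation", {
  g <- default_grid()
  p <- subject_params(w = 0)
  k <- likelihood_kernel(g, p$sd_nociceptor)
  for (n in c(15, 42.5, 80)) {
    post <- posterior(build_prior(p, g), k, n)
    expect_equal(map_estimate(post), n)
    expect_equal(sum(post$mass), 1, tolerance = 1e-9)
  }
})

test_that("posterior equals the brute-force product oracle", {
  g <- default_grid()
  p <- subject_params(w = 0.9, sigma_prior = 5.7)
  k <- likelihood_kernel(g, p$sd_nociceptor)
  prior <- build_cue_prior("green", p, g)
  post <- posterior(prior, k, 80)
  expect_equal(post$mass,
               oracle_posterior_mass(prior$mass, g, 80, p$sd_nociceptor),
               tolerance = 1e-10)
})

test_that("degenerate posterior at w = 1 with a far observation errors", {
  g <- intensity_grid(0, 400, 0.5)
  p <- subject_params(w = 1, sigma_prior = 2, sd_nociceptor = 2,
                      s_low = 20, s_high = 80)
  k <- likelihood_kernel(g, p$sd_nociceptor)
  prior <- build_cue_prior("green", p, g)
  expect_error(posterior(prior, k, 400), "degenerate")
})

test_that("MAP estimation breaks exact ties toward the lower intensity", {
  g <- intensity_grid(0, 100, 1)
  pts <- grid_points(g)
  sym <- belief(g, dnorm(pts, 20, 3) + dnorm(pts, 80, 3))
  expect_equal(map_estimate(sym), 20)

  m <- rep(1e-4, length(pts))
  m[pts == 20] <- 0.0300
  m[pts == 80] <- 0.0301
  expect_equal(map_estimate(belief(g, m)), 80)

  peaked <- belief(g, dnorm(pts, 80, 4))
  expect_equal(map_estimate(peaked), 80)
})

# rating distribution ----------------------------------------------------------

test_that("rating distribution tracks the stimulus in the naive state", {
  g <- default_grid()
  p <- subject_params(w = 0)
  # the mean tracks the stimulus up to the compression that the bounded VAS
  # scale imposes (the rating mixture is truncated at the scale ends); the
  # Monte-Carlo oracle of the same chain must agree with the exact grid mean
  withr::with_seed(404, {
    means <- vapply(c(35, 50, 65), function(s) {
      rd <- rating_distribution(s, "none", p, g)
      draws <- oracle_rating_draws(20000, s, "none", p, g)
      expect_lt(abs(belief_mean(rd) - mean(draws)), 0.5)
      belief_mean(rd)
    }, numeric(1))
  })
  expect_equal(means[2], 50, tolerance = 1e-9)
  expect_lt(max(abs(means - c(35, 50, 65))), 2)
  expect_true(all(diff(means) > 0))
})

test_that("mid-stimulus rating distribution is symmetric and bimodal at high w", {
  g <- default_grid()
  p <- subject_params(w = 0.95)
  rd <- rating_distribution(50, "none", p, g)
  expect_equal(belief_modes(rd), 2L)
  pts <- grid_points(g)
  modes <- pts[which(diff(sign(diff(rd$mass))) == -2) + 1]
  expect_equal(sum(modes), 100)  # peaks mirror about the mid stimulus
  # the construction is symmetric except for the exactly tied signal bin at
  # the midpoint, which the deterministic lower-tie MAP rule sends downward
  tied <- painbayes:::discretize_gaussian(g, 50, p$sd_nociceptor)[pts == 50]
  below <- sum(rd$mass[pts < 50])
  above <- sum(rd$mass[pts > 50])
  expect_lte(abs(below - above), tied + 1e-9)
})

test_that("the green cue lowers the predicted rating of a high stimulus", {
  g <- default_grid()
  p <- subject_params(w = 0.9)
  m_green <- belief_mean(rating_distribution(80, "green", p, g))
  m_red <- belief_mean(rating_distribution(80, "red", p, g))
  expect_lt(m_green, m_red)
})

test_that("rating distribution matches Monte Carlo draws of the same chain", {
  g <- default_grid()
  p <- subject_params(w = 0.85)
  withr::with_seed(77, {
    rd <- rating_distribution(50, "none", p, g)
    draws <- oracle_rating_draws(5000, 50, "none", p, g)
    expect_lt(sup_cdf_distance(draws, rd), 0.03)

    rd_g <- rating_distribution(80, "green", p, g)
    draws_g <- oracle_rating_draws(5000, 80, "green", p, g)
    expect_lt(sup_cdf_distance(draws_g, rd_g), 0.03)
  })
})

test_that("congruent cue information sharpens the posterior", {
  g <- default_grid()
  k <- likelihood_kernel(g, 20)
  for (w in c(0.5, 0.75, 1)) {
    p <- subject_params(w = w)
    v_red <- belief_var(posterior(build_cue_prior("red", p, g), k, 80))
    v_none <- belief_var(posterior(build_cue_prior("none", p, g), k, 80))
    expect_lt(v_red, v_none)
  }
})

# prediction surface -----------------------------------------------------------

test_that("surface rows are normalized and the naive ridge is diagonal", {
  g <- default_grid()
  p <- default_params()
  surf0 <- prediction_surface("none", p, g, w = 0)
  expect_equal(unname(rowSums(surf0$surface)), rep(1, 201), tolerance = 1e-9)
  inner <- surf0$ridge$stimulus >= 10 & surf0$ridge$stimulus <= 90
  expect_lte(max(abs(surf0$ridge$map_rating - surf0$ridge$stimulus)[inner]),
             g$step)
})

test_that("conditioning produces ridge plateaus with a jump", {
  g <- default_grid()
  surf <- prediction_surface("none", subject_params(w = 0.9), g)
  ridge <- surf$ridge$map_rating
  expect_true(all(diff(ridge) >= 0))
  jump <- max(diff(ridge))
  expect_gt(jump, 20)  # abrupt switch between the conditioned levels
  # plateaus near the conditioned anchors
  expect_lt(max(abs(ridge[surf$ridge$stimulus %in% 30:40] -
                      ridge[surf$ridge$stimulus == 35])), 3)
  expect_lt(abs(ridge[surf$ridge$stimulus == 35] - 20), 8)
  expect_lt(abs(ridge[surf$ridge$stimulus == 65] - 80), 8)
})
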