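# Independent oracles used across the suite. Each one recomputes a quantity
# by brute force (direct density evaluation, enumeration, Monte Carlo) with no
# shared code path with the implementation it checks.

default_grid <- function() intensity_grid()
default_params <- function(w = 0.9) subject_params(w = w)

# direct mixture density evaluation + renormalization on the grid
oracle_prior_mass <- function(grid, w, s_low, s_high, sigma, cue = "none") {
  pts <- grid_points(grid)
  comp <- function(m) {
    d <- stats::dnorm(pts, m, sigma)
    d / sum(d)
  }
  unif <- rep(1 / length(pts), length(pts))
  m <- switch(cue,
    none = w / 2 * comp(s_low) + w / 2 * comp(s_high) + (1 - w) * unif,
    green = w * comp(s_low) + (1 - w) * unif,
    red = w * comp(s_high) + (1 - w) * unif
  )
  m / sum(m)
}

# brute-force posterior: unnormalized product at every grid point
oracle_posterior_mass <- function(prior_mass, grid, n, sd) {
  up <- prior_mass * stats::dnorm(n, grid_points(grid), sd)
  up / sum(up)
}

# rejection-sampling Monte Carlo posterior: sample the effect from the prior,
# the signal from the Gaussian likelihood, keep draws whose signal falls into
# the observation's grid bin
oracle_mc_posterior <- function(prior_mass, grid, n_obs, sd, n_draws = 1e6) {
  pts <- grid_points(grid)
  e <- sample(pts, n_draws, replace = TRUE, prob = prior_mass)
  n <- stats::rnorm(n_draws, e, sd)
  keep <- abs(n - n_obs) <= grid$step / 2
  tabulate(match(e[keep], pts), nbins = length(pts)) / sum(keep)
}

# Monte Carlo draws from the full generative rating chain (continuous signal,
# joint rejection of the signal/rating pair into the grid range)
oracle_rating_draws <- function(n_draws, s, cue, params, grid, w = params$w) {
  pts <- grid_points(grid)
  prior <- oracle_prior_mass(grid, w, params$s_low, params$s_high,
                             params$sigma_prior, cue)
  out <- numeric(n_draws)
  i <- 0L
  while (i < n_draws) {
    n <- stats::rnorm(1, s, params$sd_nociceptor)
    if (n < grid$lo || n > grid$hi) next
    e <- pts[which.max(prior * stats::dnorm(n, pts, params$sd_nociceptor))]
    r <- stats::rnorm(1, e, params$sigma_rating)
    if (r < grid$lo || r > grid$hi) next
    i <- i + 1L
    out[i] <- r
  }
  out
}

# sup distance between an empirical sample CDF and a grid pmf CDF
sup_cdf_distance <- function(draws, bd) {
  pts <- grid_points(bd$grid)
  cdf <- cumsum(bd$mass)
  emp <- vapply(pts + bd$grid$step / 2, function(x) mean(draws <= x),
                numeric(1))
  max(abs(emp - cdf))
}

# optimal two-cluster partition of 1-d data: every optimal 2-means solution
# is an interval split of the sorted values, so enumerate all n-1 splits
oracle_best_2partition <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  best_split <- NULL
  for (k in 1:(n - 1)) {
    a <- xs[1:k]
    b <- xs[(k + 1):n]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best) {
      best <- wss
      best_split <- k
    }
  }
  list(within_ss = best,
       centers = c(mean(xs[1:best_split]), mean(xs[(best_split + 1):n])))
}

# exact one-tailed Mann-Whitney P by enumeration of all rank splits
oracle_mann_whitney_p <- function(a, b, alternative = "less") {
  pooled <- c(a, b)
  n_a <- length(a)
  stat <- function(idx) sum(rank(pooled)[idx])
  obs <- sum(rank(pooled)[seq_len(n_a)])
  splits <- utils::combn(length(pooled), n_a)
  stats_all <- apply(splits, 2, stat)
  if (alternative == "less") mean(stats_all <= obs) else mean(stats_all >= obs)
}

# exact one-tailed signed-rank P by enumeration of all sign patterns
oracle_signed_rank_p <- function(a, b, alternative = "less") {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  if (alternative == "less") mean(v_all <= v_obs) else mean(v_all >= v_obs)
}

# Pearson r and one-tailed P from the textbook formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = stats::pt(t, df = n - 2, lower.tail = FALSE))
}

# minimal placebo-block records for one subject
placebo_records <- function(green, red, subject_id = 1L, block = 4L) {
  tibble::tibble(
    subject_id = subject_id,
    experiment = 2L,
    block = block,
    trial = seq_len(length(green) + length(red)),
    cue = rep(c("green", "red"), c(length(green), length(red))),
    stimulus_level = "high",
    stimulus_intensity = 80,
    vas_raw = c(green, red),
    vas_scaled = NA_real_
  )
}
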