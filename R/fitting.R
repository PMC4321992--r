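# Per-subject parameter estimation --------------------------------------------
#
# Likelihood-based grid fitting. The model defines a full predicted rating
# distribution for every (stimulus, cue, w, sigma, sigma_rating), so fitting
# maximizes the log-likelihood of the observed placebo-block ratings over a
# deterministic parameter grid; no stochastic optimizer is involved. The
# rating-coding spread sigma_rating is profiled per subject (estimated from
# the subject's own data), mirroring how the study fitted it.

# log-likelihood machinery shared by fit_w and fit_sigma ----------------------

# Precompute rating-component bases N(u, sr) for all grid locations u.
component_bases <- function(grid, sr_grid) {
  pts <- grid_points(grid)
  lapply(sr_grid, function(sr) outer(pts, pts,
                                     function(m, r) stats::dnorm(r, m, sr)))
}

# Predicted placebo-trial pmfs for one (w, sigma_prior) and all sr in the
# basis list; returns list(green = matrix sr x points, red = ...).
placebo_pmfs <- function(w, sigma_prior, s_low, s_high, grid, kernel,
                         wts_high, bases) {
  np <- n_points(grid)
  u_floor <- uniform_mass(grid)
  out <- list()
  for (cue in c("green", "red")) {
    anchor <- if (cue == "green") s_low else s_high
    pr <- w * discretize_gaussian(grid, anchor, sigma_prior) + (1 - w) * u_floor
    idx <- decision_map_idx(pr, kernel)
    keep <- !is.na(idx) & wts_high > 0
    agg <- rowsum(wts_high[keep], idx[keep])
    rows_u <- as.integer(rownames(agg))
    pm <- matrix(0, nrow = length(bases), ncol = np)
    for (k in seq_along(bases)) {
      v <- as.numeric(crossprod(agg, bases[[k]][rows_u, , drop = FALSE]))
      pm[k, ] <- v / sum(v)
    }
    out[[cue]] <- pm
  }
  out
}

# Sum of log pmf mass at observed rating indices, per sr row.
obs_loglik <- function(pmf_matrix, idx) {
  if (length(idx) == 0L) return(rep(0, nrow(pmf_matrix)))
  lp <- log(pmf_matrix[, idx, drop = FALSE])
  rowSums(lp)
}

#' Fit the expectation weight w on placebo-block ratings
#'
#' Grid search over `w` (step 0.01) maximizing the log-likelihood of a
#' subject's placebo-block ratings under the model's predicted rating
#' distributions for the high stimulus with the green and red cues jointly.
#' The rating-coding spread `sigma_rating` is profiled over a small grid per
#' subject. Ties in the likelihood resolve to the smaller `w`.
#'
#' @param records Placebo-block rating records (high stimuli, red/green
#'   cues); may contain several subjects, one fit per `subject_id`.
#' @param params A [subject_params()] template supplying everything except
#'   `w`: prior dispersion, sensory noise and the stimulus anchors on the
#'   same scale as the ratings.
#' @param grid An [intensity_grid()] covering the ratings.
#' @param value Rating column, default `"vas_raw"`.
#' @param w_grid Candidate expectation weights.
#' @param sigma_rating_grid Candidate rating-coding spreads profiled per
#'   subject; pass a single value to fix it.
#'
#' @return An object of class `fbd_w_fit`. `tidy()` returns one row per
#'   subject (`subject_id`, `w_hat`, `sigma_rating_hat`, `loglik`,
#'   `n_trials`); `glance()` returns a one-row cohort summary.
#' @examples
#' coh <- simulate_cohort(cohort_spec(2, 2, w = 0.8, seed = 5))
#' pb <- dplyr::filter(coh$ratings, block == 4)
#' tidy(fit_w(pb, subject_params()))
#' @export
fit_w <- function(records, params, grid = intensity_grid(),
                  value = "vas_raw",
                  w_grid = seq(0, 1, by = 0.01),
                  sigma_rating_grid = c(2, 3, 4.5, 7, 10)) {
  stopifnot(is.data.frame(records), inherits(params, "subject_params"),
            value %in% names(records))
  high <- dplyr::filter(records, .data$stimulus_level == "high",
                        .data$cue %in% c("red", "green"))
  if (nrow(high) == 0L) {
    stop("no high-stimulus placebo trials with red/green cues to fit",
         call. = FALSE)
  }
  if (!"subject_id" %in% names(high)) high$subject_id <- 1L

  kernel <- get_kernel(grid, params$sd_nociceptor)
  wts_high <- discretize_gaussian(grid, params$s_high, params$sd_nociceptor)
  bases <- component_bases(grid, sigma_rating_grid)

  subjects <- split(high, high$subject_id)
  for (sub in subjects) {
    if (!any(sub$cue == "green") || !any(sub$cue == "red")) {
      stop(sprintf(
        "subject %s needs at least one green-cued and one red-cued trial",
        sub$subject_id[1]), call. = FALSE)
    }
  }
  idx_of <- function(sub, cue) {
    nearest_index(grid, sub[[value]][sub$cue == cue])
  }

  n_w <- length(w_grid)
  n_sub <- length(subjects)
  # loglik[w, sr, subject] accumulated across both cues
  ll <- array(0, dim = c(n_w, length(sigma_rating_grid), n_sub))
  for (j in seq_len(n_w)) {
    pm <- placebo_pmfs(w_grid[j], params$sigma_prior, params$s_low,
                       params$s_high, grid, kernel, wts_high, bases)
    for (k in seq_len(n_sub)) {
      ll[j, , k] <- obs_loglik(pm$green, idx_of(subjects[[k]], "green")) +
        obs_loglik(pm$red, idx_of(subjects[[k]], "red"))
    }
  }

  profiles <- list()
  rows <- purrr::map_dfr(seq_len(n_sub), function(k) {
    m <- ll[, , k, drop = FALSE][, , 1]
    prof <- apply(m, 1, max)                 # profile out sigma_rating
    j <- which.max(prof)                     # first maximum = smaller w
    sr <- sigma_rating_grid[which.max(m[j, ])]
    profiles[[as.character(names(subjects)[k])]] <<- prof
    tibble::tibble(
      subject_id = subjects[[k]]$subject_id[1],
      w_hat = w_grid[j],
      sigma_rating_hat = sr,
      loglik = prof[j],
      n_trials = nrow(subjects[[k]])
    )
  })
  structure(list(results = rows, profiles = profiles, w_grid = w_grid,
                 params = params),
            class = "fbd_w_fit")
}

#' @export
print.fbd_w_fit <- function(x, ...) {
  cat(sprintf("<fbd_w_fit> %d subject(s); mean w_hat = %.3f\n",
              nrow(x$results), mean(x$results$w_hat)))
  print(x$results)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fbd_w_fit <- function(x, ...) x$results

#' @export
glance.fbd_w_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$results),
    mean_w_hat = mean(x$results$w_hat),
    sd_w_hat = stats::sd(x$results$w_hat),
    total_loglik = sum(x$results$loglik)
  )
}

#' Fit the prior dispersion sigma on conditioning + placebo records
#'
#' Per-subject grid fit of the prior dispersion on the placebo-block
#' likelihood. The dispersion is selected by its integrated (type-II)
#' likelihood — the log-mean of the likelihood over the grid of expectation
#' weights and rating-coding spreads — which guards against degenerate
#' spike-and-slab fits that a fully profiled likelihood rewards at very
#' small dispersions; the expectation weight and coding spread reported for
#' each subject are then the joint maximizers conditional on the selected
#' dispersion. The prior component locations are fixed at the subject's
#' conditioning-block mean ratings, as in the study's data-driven
#' parameterization. Subjects with degenerate conditioning statistics
#' (constant ratings) are flagged, not dropped with an error.
#'
#' @param records Experiment-1-style records (conditioning blocks plus a
#'   placebo block) for one or more subjects.
#' @param params A [subject_params()] template (sensory noise).
#' @param grid An [intensity_grid()].
#' @param value Rating column, default `"vas_raw"`.
#' @param sigma_grid Candidate prior dispersions.
#' @param w_grid Candidate expectation weights.
#' @param sigma_rating_grid Candidate rating-coding spreads.
#'
#' @return An object of class `fbd_sigma_fit`; `tidy()` gives per-subject
#'   rows, `glance()` the cohort mean and s.d. of the fitted dispersion.
#' @export
fit_sigma <- function(records, params = subject_params(),
                      grid = intensity_grid(), value = "vas_raw",
                      sigma_grid = seq(1.5, 12, by = 0.75),
                      w_grid = seq(0, 1, by = 0.05),
                      sigma_rating_grid = c(2, 3, 4.5, 7, 10)) {
  stopifnot(is.data.frame(records), inherits(params, "subject_params"))
  if (!"subject_id" %in% names(records)) records$subject_id <- 1L
  experiment <- if ("experiment" %in% names(records)) {
    records$experiment[1]
  } else 1L
  pb <- placebo_block(experiment)
  kernel <- get_kernel(grid, params$sd_nociceptor)
  bases <- component_bases(grid, sigma_rating_grid)

  rows <- records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(df, key) {
      placebo <- dplyr::filter(df, .data$block == pb,
                               .data$stimulus_level == "high",
                               .data$cue %in% c("red", "green"))
      if (nrow(placebo) < 2L || !any(placebo$cue == "green") ||
          !any(placebo$cue == "red")) {
        stop(sprintf("subject %s: insufficient placebo trials to fit sigma",
                     key$subject_id), call. = FALSE)
      }
      stats_c <- suppressWarnings(conditioning_stats(df, value = value))
      if (stats_c$degenerate) {
        return(tibble::tibble(subject_id = key$subject_id, sigma_hat = NA_real_,
                              w_hat = NA_real_, sigma_rating_hat = NA_real_,
                              loglik = NA_real_, degenerate = TRUE))
      }
      g_idx <- nearest_index(grid, placebo[[value]][placebo$cue == "green"])
      r_idx <- nearest_index(grid, placebo[[value]][placebo$cue == "red"])
      wts_high <- discretize_gaussian(grid, stats_c$mean_high,
                                      params$sd_nociceptor)
      # ll[[i]] holds the (w x sigma_rating) log-likelihood grid at sigma_i
      ll <- lapply(sigma_grid, function(sg) {
        t(vapply(w_grid, function(w) {
          pm <- placebo_pmfs(w, sg, stats_c$mean_low, stats_c$mean_high,
                             grid, kernel, wts_high, bases)
          obs_loglik(pm$green, g_idx) + obs_loglik(pm$red, r_idx)
        }, numeric(length(sigma_rating_grid))))
      })
      ll_int <- vapply(ll, function(m) {
        v <- m[is.finite(m)]
        if (length(v) == 0L) return(-Inf)
        mx <- max(v)
        mx + log(sum(exp(v - mx))) - log(length(m))
      }, numeric(1))
      i <- which.max(ll_int)               # ties resolve to the smaller sigma
      m <- ll[[i]]
      j <- arrayInd(which.max(m), dim(m))
      tibble::tibble(subject_id = key$subject_id,
                     sigma_hat = sigma_grid[i],
                     w_hat = w_grid[j[1]],
                     sigma_rating_hat = sigma_rating_grid[j[2]],
                     loglik = max(m[is.finite(m)]),
                     degenerate = FALSE)
    }) |>
    dplyr::bind_rows()

  structure(list(results = rows,
                 sigma_grid = sigma_grid, w_grid = w_grid),
            class = "fbd_sigma_fit")
}

#' @export
print.fbd_sigma_fit <- function(x, ...) {
  ok <- !x$results$degenerate
  cat(sprintf("<fbd_sigma_fit> %d subject(s); sigma_hat = %.2f +/- %.2f\n",
              nrow(x$results), mean(x$results$sigma_hat[ok]),
              stats::sd(x$results$sigma_hat[ok])))
  invisible(x)
}

#' @export
tidy.fbd_sigma_fit <- function(x, ...) x$results

#' @export
glance.fbd_sigma_fit <- function(x, ...) {
  ok <- !x$results$degenerate & !is.na(x$results$sigma_hat)
  tibble::tibble(
    n_subjects = nrow(x$results),
    n_degenerate = sum(x$results$degenerate),
    sigma_mean = mean(x$results$sigma_hat[ok]),
    sigma_sd = stats::sd(x$results$sigma_hat[ok])
  )
}

#' Variance in the placebo effect explained by the expectation weight
#'
#' Pearson correlation between fitted expectation weights and placebo
#' magnitudes, with a one-tailed P-value for the positive alternative, and
#' the residual variance defined as `100 * (1 - r^2)` percent.
#'
#' @param w_hat Fitted expectation weights, one per subject.
#' @param placebo Placebo magnitudes, same length.
#'
#' @return One-row tibble with `r`, `p_one_tailed`, `residual_variance_pct`,
#'   `n`.
#' @export
explained_variance <- function(w_hat, placebo) {
  if (length(w_hat) != length(placebo)) {
    stop("`w_hat` and `placebo` must have equal length", call. = FALSE)
  }
  if (length(w_hat) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(w_hat) == 0 || stats::sd(placebo) == 0) {
    stop("correlation undefined: one of the vectors is constant", call. = FALSE)
  }
  ct <- pearson_one_tailed(w_hat, placebo)
  tibble::tibble(
    r = ct$r,
    p_one_tailed = ct$p,
    residual_variance_pct = 100 * (1 - ct$r^2),
    n = length(w_hat)
  )
}
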