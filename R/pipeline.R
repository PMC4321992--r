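# End-to-end replication pipeline ---------------------------------------------
#
# Orchestrates the full analysis on synthetic cohorts: simulate the two
# experiments, scale ratings, fit the prior dispersion on Experiment 1 and
# the expectation weight per subject, predict, compare models on held-out
# no-cue ratings, cluster the mid-stimulus ratings, and assemble the cohort
# statistics. Everything is deterministic given (config, seed).

#' Configuration for a replication run
#'
#' @param n_exp1,n_exp2 Cohort sizes for the two experiments.
#' @param w Cohort distribution of the expectation weight passed to
#'   [cohort_spec()]: `"uniform"`, a single value, or a per-subject vector.
#' @param sigma_prior,sd_nociceptor,sigma_rating,s_low,s_high Generative
#'   parameters shared by both cohorts (see [subject_params()]).
#' @param grid_lo,grid_hi,grid_step Grid of the common intensity axis.
#' @param file Optional path to a JSON file whose fields override the
#'   defaults (same names as the arguments).
#'
#' @return A list of class `replication_config`.
#' @export
replication_config <- function(n_exp1 = 24, n_exp2 = 31, w = "uniform",
                               sigma_prior = 5.7, sd_nociceptor = 20,
                               sigma_rating = 3, s_low = 20, s_high = 80,
                               grid_lo = 0, grid_hi = 100, grid_step = 0.5,
                               file = NULL) {
  cfg <- list(n_exp1 = n_exp1, n_exp2 = n_exp2, w = w,
              sigma_prior = sigma_prior, sd_nociceptor = sd_nociceptor,
              sigma_rating = sigma_rating, s_low = s_low, s_high = s_high,
              grid_lo = grid_lo, grid_hi = grid_hi, grid_step = grid_step)
  if (!is.null(file)) {
    override <- jsonlite::fromJSON(file, simplifyVector = TRUE)
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) {
      stop("unknown config fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(override)] <- override
  }
  structure(cfg, class = "replication_config")
}

config_grid <- function(cfg) {
  intensity_grid(cfg$grid_lo, cfg$grid_hi, cfg$grid_step)
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", label, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full replication pipeline on synthetic cohorts
#'
#' Simulates an Experiment-1 cohort (conditioning + placebo test) and an
#' Experiment-2 cohort (conditioning + no-cue test + placebo test), then
#' reproduces the analysis chain: VAS scaling; per-subject prior-dispersion
#' and expectation-weight fits (the Experiment-1 dispersion estimate feeds
#' the Experiment-2 models, as in the study); placebo magnitudes and paired
#' one-tailed signed-rank tests; Bayes-factor comparison of the fBD,
#' no-learn and simple Bayesian models on the held-out no-cue mid-stimulus
#' ratings; two-cluster and bimodality analyses of those ratings; and the
#' correlation table of placebo size and fitted weight against the
#' clustering measures.
#'
#' @param config A [replication_config()].
#' @param seed Master seed; the whole report is reproducible from
#'   (config, seed).
#' @param out_dir Optional directory; when given, per-stage CSV tables and a
#'   `report.json` are written under it.
#'
#' @return A list of class `replication_report`.
#' @export
run_replication <- function(config = replication_config(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(config, "replication_config"))
  grid <- config_grid(config)
  template <- subject_params(
    w = 0.5, sigma_prior = config$sigma_prior,
    sd_nociceptor = config$sd_nociceptor, sigma_rating = config$sigma_rating,
    s_low = config$s_low, s_high = config$s_high
  )

  coh1 <- stage("simulate experiment 1", simulate_cohort(
    cohort_spec(config$n_exp1, 1, w = config$w,
                sigma_prior = config$sigma_prior,
                sd_nociceptor = config$sd_nociceptor,
                sigma_rating = config$sigma_rating,
                s_low = config$s_low, s_high = config$s_high,
                seed = seed), grid))
  coh2 <- stage("simulate experiment 2", simulate_cohort(
    cohort_spec(config$n_exp2, 2, w = config$w,
                sigma_prior = config$sigma_prior,
                sd_nociceptor = config$sd_nociceptor,
                sigma_rating = config$sigma_rating,
                s_low = config$s_low, s_high = config$s_high,
                seed = child_seed(seed, 10007)), grid))

  scaled1 <- stage("scale experiment 1", scale_vas(coh1$ratings))
  scaled2 <- stage("scale experiment 2", scale_vas(coh2$ratings))

  # Experiment 1: joint (sigma, w) fit per subject on the placebo block
  sfit <- stage("fit sigma on experiment 1",
                fit_sigma(coh1$ratings, template, grid))
  sigma_summary <- glance(sfit)

  exp1_placebo <- stage("experiment 1 placebo magnitudes", {
    scaled1 |>
      dplyr::filter(.data$block == placebo_block(1)) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_modify(~ tibble::tibble(
        placebo_magnitude = placebo_magnitude(.x, value = "vas_scaled"))) |>
      dplyr::ungroup()
  })
  exp1 <- dplyr::left_join(tidy(sfit), exp1_placebo, by = "subject_id")
  exp1_ok <- !exp1$degenerate & !is.na(exp1$w_hat)
  exp1_ev <- stage("experiment 1 explained variance",
                   explained_variance(exp1$w_hat[exp1_ok],
                                      exp1$placebo_magnitude[exp1_ok]))
  exp1_test <- stage("experiment 1 placebo test",
                     cohort_placebo_test(scaled1, 1))

  # Experiment 2: per-subject fits with the Experiment-1 dispersion estimate
  sigma_for_exp2 <- sigma_summary$sigma_mean
  exp2 <- stage("experiment 2 subject analyses", {
    coh2$ratings |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_map(~ analyze_exp2_subject(
        .x, .y$subject_id, scaled2, sigma_for_exp2, template, grid,
        seed = seed)) |>
      dplyr::bind_rows()
  })

  exp2_ev <- stage("experiment 2 explained variance",
                   explained_variance(exp2$w_hat, exp2$placebo_magnitude))
  exp2_test <- stage("experiment 2 placebo test",
                     cohort_placebo_test(scaled2, 2))

  pooled_mid <- scaled2$vas_scaled[scaled2$block == 3 &
                                     scaled2$stimulus_level == "mid"]
  pooled_bimodality <- stage("pooled bimodality test",
                             tidy(bimodality_test(pooled_mid, seed = seed)))

  table1 <- stage("clustering correlation table", {
    combos <- tidyr::expand_grid(
      predictor = c("placebo_magnitude", "w_hat"),
      measure = c("center_distance", "separation_index",
                  "posterior_prob_bimodal")
    )
    purrr::pmap_dfr(combos, function(predictor, measure) {
      ct <- pearson_one_tailed(exp2[[predictor]], exp2[[measure]])
      tibble::tibble(predictor = predictor, measure = measure,
                     r = ct$r, p_one_tailed = ct$p)
    })
  })

  model_wins <- exp2 |>
    dplyr::count(.data$best_model) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))

  report <- structure(list(
    seed = as.integer(seed),
    config = unclass(config),
    exp1 = list(subjects = exp1, sigma_summary = sigma_summary,
                explained_variance = exp1_ev, placebo_test = exp1_test),
    exp2 = list(subjects = exp2, explained_variance = exp2_ev,
                placebo_test = exp2_test,
                pooled_bimodality = pooled_bimodality,
                table1 = table1, model_wins = model_wins)
  ), class = "replication_report")

  if (!is.null(out_dir)) write_report(report, coh1, coh2, scaled1, scaled2,
                                      out_dir)
  report
}

# per-subject Experiment-2 analysis: fit w on the placebo block, score the
# three models on the held-out no-cue mid ratings, cluster the scaled ones
analyze_exp2_subject <- function(raw, subject_id, scaled_all, sigma_prior,
                                 template, grid, seed) {
  stats_c <- suppressWarnings(conditioning_stats(raw))
  if (stats_c$degenerate) {
    stop(sprintf("subject %s: degenerate conditioning statistics", subject_id),
         call. = FALSE)
  }
  s_low_i <- min(stats_c$mean_low, stats_c$mean_high - 1)
  params_i <- set_params(template, sigma_prior = sigma_prior,
                         s_low = s_low_i, s_high = stats_c$mean_high,
                         s_mid = (s_low_i + stats_c$mean_high) / 2)
  placebo <- dplyr::filter(raw, .data$block == placebo_block(2))
  wfit <- fit_w(placebo, params_i, grid)
  w_hat <- wfit$results$w_hat[1]
  sr_hat <- wfit$results$sigma_rating_hat[1]

  mid_raw <- raw$vas_raw[raw$block == 3 & raw$stimulus_level == "mid"]
  s_mid <- (stats_c$mean_low + stats_c$mean_high) / 2
  predictives <- list(
    fBD = rating_distribution(s_mid, "none",
                              set_params(params_i, sigma_rating = sr_hat),
                              grid, w = w_hat),
    no_learn = no_learn_predictive(stats_c, s_mid, params_i, grid),
    simple_bayes = simple_bayes_predictive(stats_c, s_mid, params_i, grid)
  )
  scores <- model_posteriors(mid_raw, predictives)
  best <- scores$model[which.max(scores$posterior)]

  mid_scaled <- scaled_all$vas_scaled[scaled_all$subject_id == subject_id &
                                        scaled_all$block == 3 &
                                        scaled_all$stimulus_level == "mid"]
  bt <- suppressWarnings(bimodality_test(mid_scaled, seed = seed))
  placebo_scaled <- scaled_all |>
    dplyr::filter(.data$subject_id == .env$subject_id,
                  .data$block == placebo_block(2))

  tibble::tibble(
    subject_id = subject_id,
    w_hat = w_hat,
    sigma_rating_hat = sr_hat,
    placebo_magnitude = placebo_magnitude(placebo_scaled,
                                          value = "vas_scaled"),
    center_distance = bt$clusters$center_distance,
    separation_index = bt$clusters$separation_index,
    posterior_prob_bimodal = bt$posterior_prob_bimodal,
    bimodality_bf = bt$bayes_factor,
    posterior_fBD = scores$posterior[scores$model == "fBD"],
    posterior_no_learn = scores$posterior[scores$model == "no_learn"],
    posterior_simple_bayes = scores$posterior[scores$model == "simple_bayes"],
    best_model = best
  )
}

# paired one-tailed signed-rank test of green vs red high-stimulus means
cohort_placebo_test <- function(scaled, experiment) {
  pb <- placebo_block(experiment)
  means <- scaled |>
    dplyr::filter(.data$block == pb, .data$stimulus_level == "high") |>
    dplyr::group_by(.data$subject_id, .data$cue) |>
    dplyr::summarise(m = mean(.data$vas_scaled), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cue", values_from = "m")
  rt <- rank_tests(means$green, means$red, paired = TRUE,
                   alternative = "less")
  tibble::tibble(n = nrow(means), statistic = rt$statistic,
                 p_one_tailed = rt$p,
                 mean_green = mean(means$green), mean_red = mean(means$red))
}

#' @export
print.replication_report <- function(x, ...) {
  cat("<replication_report>\n")
  cat(sprintf("  seed %d; cohorts n = %d (exp 1) / %d (exp 2)\n",
              x$seed, x$config$n_exp1, x$config$n_exp2))
  cat(sprintf("  sigma_hat = %.2f +/- %.2f\n",
              x$exp1$sigma_summary$sigma_mean, x$exp1$sigma_summary$sigma_sd))
  cat(sprintf("  placebo test P (exp 1 / exp 2): %.2g / %.2g\n",
              x$exp1$placebo_test$p_one_tailed,
              x$exp2$placebo_test$p_one_tailed))
  cat(sprintf("  w vs placebo: r = %.2f (exp 1), %.2f (exp 2)\n",
              x$exp1$explained_variance$r, x$exp2$explained_variance$r))
  cat(sprintf("  pooled bimodality: Pr = %.2f, BF = %.2f\n",
              x$exp2$pooled_bimodality$posterior_prob_bimodal,
              x$exp2$pooled_bimodality$bayes_factor))
  invisible(x)
}

write_report <- function(report, coh1, coh2, scaled1, scaled2, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("ratings", "fits", "comparison")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  utils::write.csv(scaled1, file.path(out_dir, "ratings", "experiment1.csv"),
                   row.names = FALSE)
  utils::write.csv(scaled2, file.path(out_dir, "ratings", "experiment2.csv"),
                   row.names = FALSE)
  utils::write.csv(coh1$truth, file.path(out_dir, "ratings", "truth1.csv"),
                   row.names = FALSE)
  utils::write.csv(coh2$truth, file.path(out_dir, "ratings", "truth2.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exp1$subjects,
                   file.path(out_dir, "fits", "experiment1_subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exp2$subjects,
                   file.path(out_dir, "fits", "experiment2_subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exp2$table1,
                   file.path(out_dir, "comparison", "cluster_correlations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Prediction surfaces for all cue conditions
#'
#' Computes the Pr(R|S) surface and most-probable-rating ridge for the
#' pre-conditioning state (`w = 0`) and for the post-conditioning no-cue,
#' green-cue and red-cue conditions, optionally writing each surface as a CSV
#' matrix (stimulus rows x rating columns, header row of rating grid values).
#'
#' @param params A [subject_params()] object (its `w` is the
#'   post-conditioning expectation weight).
#' @param grid An [intensity_grid()].
#' @param out_dir Optional output directory for the CSV files.
#'
#' @return Named list of [prediction_surface()] objects
#'   (`pre`, `none`, `green`, `red`).
#' @export
predict_surfaces <- function(params = subject_params(w = 0.9),
                             grid = intensity_grid(), out_dir = NULL) {
  surfaces <- list(
    pre = prediction_surface("none", params, grid, w = 0),
    none = prediction_surface("none", params, grid),
    green = prediction_surface("green", params, grid),
    red = prediction_surface("red", params, grid)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(surfaces)) {
      write_surface_csv(surfaces[[nm]],
                        file.path(out_dir, paste0("surface_", nm, ".csv")))
    }
    ridges <- purrr::imap_dfr(surfaces, ~ dplyr::mutate(.x$ridge,
                                                        condition = .y))
    utils::write.csv(ridges, file.path(out_dir, "ridges.csv"),
                     row.names = FALSE)
  }
  surfaces
}

#' Write a prediction surface as a CSV matrix
#'
#' First column `stimulus`, remaining columns the rating grid values; each
#' row is the normalized predicted rating pmf for that stimulus.
#'
#' @param surface An `fbd_surface` from [prediction_surface()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "fbd_surface"))
  pts <- grid_points(surface$grid)
  df <- data.frame(stimulus = pts, surface$surface, check.names = FALSE)
  names(df)[-1] <- format(pts, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
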