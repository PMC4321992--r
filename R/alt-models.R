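# Competitor models for model comparison --------------------------------------
#
# Two alternatives to the full Bayesian decision model, both anchored to the
# ratings a subject actually produced during the conditioning blocks:
#  * no-learn: conditioning leaves perception untouched; ratings follow one
#    Gaussian whose mean interpolates linearly between the conditioning means.
#  * simple Bayes: the conditioned expectation (two-component prior) is
#    combined with the stimulus likelihood, and the posterior itself is the
#    predicted rating distribution (no decision or coding-noise stage).

#' Conditioning-block rating summary
#'
#' Per-subject means and standard deviations of the ratings given to the low
#' and high stimuli during the conditioning blocks. These anchor both
#' competitor models and the data-driven parameterization of the fBD model.
#'
#' @param records Rating records (see [simulate_subject()]): requires columns
#'   `block`, `stimulus_level` and a rating column.
#' @param value Column to summarize, `"vas_raw"` (default) or `"vas_scaled"`.
#' @param blocks Conditioning block indices (default 1:2).
#'
#' @return An object of class `conditioning_stats`: list with `mean_low`,
#'   `sd_low`, `mean_high`, `sd_high`, `n_low`, `n_high` and a logical
#'   `degenerate` flag (zero or undefined spread).
#' @export
conditioning_stats <- function(records, value = "vas_raw", blocks = 1:2) {
  stopifnot(is.data.frame(records), value %in% names(records))
  cond <- dplyr::filter(records, .data$block %in% blocks,
                        .data$stimulus_level %in% c("low", "high"))
  if (nrow(cond) == 0L) {
    stop("no conditioning-block records for levels low/high", call. = FALSE)
  }
  smry <- cond |>
    dplyr::group_by(.data$stimulus_level) |>
    dplyr::summarise(m = mean(.data[[value]]), s = stats::sd(.data[[value]]),
                     n = dplyr::n(), .groups = "drop")
  pick <- function(lv, col) {
    v <- smry[[col]][smry$stimulus_level == lv]
    if (length(v) == 0L) NA_real_ else v
  }
  out <- list(mean_low = pick("low", "m"), sd_low = pick("low", "s"),
              mean_high = pick("high", "m"), sd_high = pick("high", "s"),
              n_low = pick("low", "n"), n_high = pick("high", "n"))
  out$degenerate <- anyNA(unlist(out[1:4])) ||
    out$sd_low <= 0 || out$sd_high <= 0
  if (!out$degenerate && out$mean_low >= out$mean_high) {
    warning("conditioning means are not ordered (mean_low >= mean_high); ",
            "the subject may not have discriminated the stimuli",
            call. = FALSE)
  }
  structure(out, class = "conditioning_stats")
}

#' @export
print.conditioning_stats <- function(x, ...) {
  cat(sprintf("<conditioning_stats> low %.1f (sd %.1f, n %d); high %.1f (sd %.1f, n %d)%s\n",
              x$mean_low, x$sd_low, x$n_low, x$mean_high, x$sd_high, x$n_high,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

pooled_sd <- function(stats) sqrt((stats$sd_low^2 + stats$sd_high^2) / 2)

check_stats <- function(stats) {
  stopifnot(inherits(stats, "conditioning_stats"))
  if (stats$degenerate) {
    stop("degenerate conditioning statistics (missing level or zero spread)",
         call. = FALSE)
  }
  invisible(stats)
}

#' No-learn model predictive
#'
#' Under the no-learn hypothesis conditioning has no effect on perception:
#' the predicted rating distribution for any stimulus is a single Gaussian
#' whose mean interpolates linearly between the conditioning-block means
#' (a mid stimulus predicts the exact midpoint) with the pooled
#' (root-mean-square) conditioning spread.
#'
#' @param stats A [conditioning_stats()] summary.
#' @param s Stimulus intensity.
#' @param params A [subject_params()] object (supplies the stimulus anchors).
#' @param grid An [intensity_grid()].
#'
#' @return A [belief()] distribution over ratings.
#' @export
no_learn_predictive <- function(stats, s, params, grid) {
  check_stats(stats)
  stopifnot(inherits(params, "subject_params"), inherits(grid, "intensity_grid"))
  frac <- (s - params$s_low) / (params$s_high - params$s_low)
  m <- stats$mean_low + frac * (stats$mean_high - stats$mean_low)
  belief(grid, discretize_gaussian(grid, m, pooled_sd(stats)))
}

#' Simple Bayesian model predictive
#'
#' Integrates the conditioned expectation with the sensory input and stops
#' there: the predictive is the normalized point-wise product of the
#' two-component conditioning prior (equal weights, no uniform floor, no
#' expectation weight) and the Gaussian stimulus likelihood. Unlike the full
#' decision model there is no MAP stage and no rating-coding noise.
#'
#' @inheritParams no_learn_predictive
#' @param cue Optional cue label; only honoured when `use_cue = TRUE`, in
#'   which case a red/green cue selects its single associated component.
#' @param use_cue Should the prior condition on the cue? Default `FALSE`:
#'   both alternatives ignore cues for uncued trials, and the plain variant
#'   is also the default for placebo trials.
#'
#' @return A [belief()] distribution over ratings.
#' @export
simple_bayes_predictive <- function(stats, s, params, grid,
                                    cue = "none", use_cue = FALSE) {
  check_stats(stats)
  stopifnot(inherits(params, "subject_params"), inherits(grid, "intensity_grid"))
  check_cue(cue)
  prior_mass <-
    if (use_cue && cue == "green") {
      discretize_gaussian(grid, stats$mean_low, stats$sd_low)
    } else if (use_cue && cue == "red") {
      discretize_gaussian(grid, stats$mean_high, stats$sd_high)
    } else {
      0.5 * discretize_gaussian(grid, stats$mean_low, stats$sd_low) +
        0.5 * discretize_gaussian(grid, stats$mean_high, stats$sd_high)
    }
  loglik <- stats::dnorm(s, grid_points(grid), params$sd_nociceptor, log = TRUE)
  logpost <- log(prior_mass) + loglik
  m <- max(logpost)
  if (!is.finite(m)) {
    stop("degenerate posterior: stimulus likelihood vanishes on the prior ",
         "support", call. = FALSE)
  }
  belief(grid, exp(logpost - m))
}
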