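# Subject-level model parameters ----------------------------------------------

#' Subject parameters of the Bayesian decision model
#'
#' Collects the generative/inference parameters of one subject. All values are
#' expressed in the arbitrary 0-100 intensity units of the common grid.
#'
#' @param w Expectation/conditioning weight in `[0, 1]`: mixture weight of the
#'   conditioned Gaussian prior components; `1 - w` goes to the uniform
#'   "anything possible" component.
#' @param sigma_prior Standard deviation of the conditioned prior components
#'   (the prior dispersion; cohort estimate 5.7 in the study this package
#'   models).
#' @param sd_nociceptor Standard deviation of the nociceptor likelihood
#'   Pr(N|E) and of the stimulus-to-signal distribution Pr(N|S), expressed on
#'   the intensity scale. The underlying neurophysiological value of 0.75 is
#'   stated in nociceptor firing units whose proportionality to the intensity
#'   axis is free; the default of 20 intensity units (0.75 with a gain of
#'   0.0375 nociceptor units per intensity unit) reproduces the placebo
#'   magnitudes and mid-stimulus bimodality observed experimentally.
#' @param sigma_rating Standard deviation of the rating-coding noise
#'   Pr(R|E-hat): variability of translating a perceived intensity into a VAS
#'   score.
#' @param s_low,s_mid,s_high Stimulus anchor intensities used during
#'   conditioning (low, high) and in the no-cue test (mid). `s_mid` defaults
#'   to the midpoint of `s_low` and `s_high`, as in the test protocol.
#'
#' @return An object of class `subject_params`.
#' @examples
#' subject_params(w = 0.9)
#' @export
subject_params <- function(w = 0.9,
                           sigma_prior = 5.7,
                           sd_nociceptor = 20,
                           sigma_rating = 3,
                           s_low = 20,
                           s_high = 80,
                           s_mid = (s_low + s_high) / 2) {
  check_w(w)
  for (nm in c("sigma_prior", "sd_nociceptor", "sigma_rating")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a positive scalar", nm), call. = FALSE)
    }
  }
  if (!(s_low < s_mid && s_mid < s_high)) {
    stop("stimulus anchors must satisfy s_low < s_mid < s_high", call. = FALSE)
  }
  structure(
    list(w = w, sigma_prior = sigma_prior, sd_nociceptor = sd_nociceptor,
         sigma_rating = sigma_rating, s_low = s_low, s_mid = s_mid,
         s_high = s_high),
    class = "subject_params"
  )
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<subject_params> w=%.2f sigma_prior=%.2f sd_nociceptor=%.2f ",
    "sigma_rating=%.2f anchors=(%g, %g, %g)\n"),
    x$w, x$sigma_prior, x$sd_nociceptor, x$sigma_rating,
    x$s_low, x$s_mid, x$s_high))
  invisible(x)
}

check_w <- function(w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("`w` must be a single number in [0, 1]", call. = FALSE)
  }
  invisible(w)
}

# replace w (and optionally other fields) in a subject_params object
set_params <- function(params, ...) {
  new <- list(...)
  stopifnot(all(names(new) %in% names(params)))
  params[names(new)] <- new
  do.call(subject_params, params[c("w", "sigma_prior", "sd_nociceptor",
                                   "sigma_rating", "s_low", "s_high", "s_mid")])
}

#' Cue conditions
#'
#' The closed set of cue labels: `"red"` (associated with high pain during
#' training), `"green"` (associated with low pain) and `"none"` (the neutral
#' blue cue / no-cue condition).
#'
#' @return Character vector of the three valid labels.
#' @export
cue_conditions <- function() c("red", "green", "none")

check_cue <- function(cue) {
  if (!is.character(cue) || length(cue) != 1L || !cue %in% cue_conditions()) {
    stop("`cue` must be one of \"red\", \"green\", \"none\"", call. = FALSE)
  }
  cue
}
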