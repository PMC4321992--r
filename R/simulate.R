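# Synthetic cohort generation -------------------------------------------------
#
# Trial-level VAS records drawn from the full generative chain of the model:
# nociceptor signal ~ N(stimulus, sd_nociceptor), MAP percept under the
# subject's current prior (flat during conditioning, conditioned afterwards),
# rating ~ N(percept, sigma_rating). The signal/rating pair is rejection
# sampled jointly into the grid range (a VAS score cannot leave the scale),
# which makes simulated ratings exactly distributed as rating_distribution().

#' Simulate one subject through an experiment
#'
#' @param params A [subject_params()] object (the subject's generative truth).
#' @param design An [make_design()] schedule.
#' @param seed Integer seed; the record list is deterministic given
#'   `(params, design, seed)`.
#' @param grid An [intensity_grid()].
#' @param subject_id Identifier stored in the records.
#'
#' @return A tibble of rating records with columns `subject_id`, `experiment`,
#'   `block`, `trial`, `cue`, `stimulus_level`, `stimulus_intensity`,
#'   `vas_raw`, `vas_scaled` (NA until [scale_vas()] is applied).
#' @examples
#' sub <- simulate_subject(subject_params(w = 0.8), make_design(2, 1), seed = 7)
#' dplyr::count(sub, block, cue)
#' @export
simulate_subject <- function(params, design, seed, grid = intensity_grid(),
                             subject_id = 1L) {
  stopifnot(inherits(params, "subject_params"),
            inherits(design, "experiment_design"),
            inherits(grid, "intensity_grid"))
  experiment <- attr(design, "experiment")
  kernel <- get_kernel(grid, params$sd_nociceptor)
  pts <- grid_points(grid)
  anchors <- c(low = params$s_low, mid = params$s_mid, high = params$s_high)
  active <- post_conditioning_blocks(experiment)

  # cue-specific priors once; flat prior during conditioning
  priors <- list(flat = uniform_mass(grid))
  for (cue in cue_conditions()) {
    priors[[cue]] <- build_cue_prior(cue, params, grid)$mass
  }

  withr::with_seed(seed, {
    vas <- numeric(nrow(design))
    for (i in seq_len(nrow(design))) {
      pr <- if (design$block[i] %in% active) priors[[design$cue[i]]] else priors$flat
      s <- anchors[[design$stimulus_level[i]]]
      repeat {
        n <- stats::rnorm(1, s, params$sd_nociceptor)
        if (n < grid$lo || n > grid$hi) next
        up <- pr * stats::dnorm(n, pts, params$sd_nociceptor)
        if (max(up) <= 0) {
          stop("degenerate posterior during simulation (w = 1 with an ",
               "observation outside the prior support)", call. = FALSE)
        }
        e <- pts[which.max(up)]
        r <- stats::rnorm(1, e, params$sigma_rating)
        if (r >= grid$lo && r <= grid$hi) break
      }
      vas[i] <- r
    }
    tibble::tibble(
      subject_id = subject_id,
      experiment = experiment,
      block = design$block,
      trial = design$trial,
      cue = design$cue,
      stimulus_level = design$stimulus_level,
      stimulus_intensity = unname(anchors[design$stimulus_level]),
      vas_raw = vas,
      vas_scaled = NA_real_
    )
  })
}

#' Simulate one subject under the no-learn model
#'
#' Generator for identifiability studies: conditioning leaves perception
#' untouched, so every rating is drawn from one Gaussian centred on the
#' linear stimulus-rating map through the anchors, with a single
#' subject-level rating spread. The default spread of 10 intensity units is
#' a typical within-subject VAS variability for repeated identical stimuli.
#'
#' @param design An [make_design()] schedule.
#' @param seed Integer seed.
#' @param params A [subject_params()] object supplying the stimulus anchors.
#' @param sd_rating Rating spread around the stimulus-determined mean.
#' @param grid An [intensity_grid()]; ratings are truncated into its range.
#' @param subject_id Identifier stored in the records.
#'
#' @return A tibble of rating records in the same schema as
#'   [simulate_subject()].
#' @export
simulate_no_learn_subject <- function(design, seed, params = subject_params(),
                                      sd_rating = 10,
                                      grid = intensity_grid(),
                                      subject_id = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "subject_params"))
  anchors <- c(low = params$s_low, mid = params$s_mid, high = params$s_high)
  withr::with_seed(seed, {
    vas <- vapply(seq_len(nrow(design)), function(i) {
      s <- anchors[[design$stimulus_level[i]]]
      repeat {
        r <- stats::rnorm(1, s, sd_rating)
        if (r >= grid$lo && r <= grid$hi) return(r)
      }
    }, numeric(1))
    tibble::tibble(
      subject_id = subject_id,
      experiment = attr(design, "experiment"),
      block = design$block,
      trial = design$trial,
      cue = design$cue,
      stimulus_level = design$stimulus_level,
      stimulus_intensity = unname(anchors[design$stimulus_level]),
      vas_raw = vas,
      vas_scaled = NA_real_
    )
  })
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of subjects.
#' @param experiment 1 or 2.
#' @param w Either a single number (all subjects share it), a vector of
#'   length `n_subjects`, or the string `"uniform"` to draw each subject's
#'   expectation weight from Uniform(0, 1).
#' @param sigma_prior,sd_nociceptor,sigma_rating,s_low,s_high Cohort-level
#'   generative parameters (see [subject_params()]).
#' @param seed Master seed; per-subject seeds and weights derive from it
#'   deterministically.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, experiment, w = "uniform",
                        sigma_prior = 5.7, sd_nociceptor = 20,
                        sigma_rating = 3, s_low = 20, s_high = 80,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, experiment %in% c(1, 2))
  if (is.character(w)) {
    w <- match.arg(w, "uniform")
  } else {
    stopifnot(is.numeric(w), length(w) %in% c(1L, n_subjects),
              all(w >= 0 & w <= 1))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         experiment = as.integer(experiment), w = w,
         sigma_prior = sigma_prior, sd_nociceptor = sd_nociceptor,
         sigma_rating = sigma_rating, s_low = s_low, s_high = s_high,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# deterministic child-seed derivation, kept inside 32-bit integer range
child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 100003 * as.numeric(i)) %% 2147483647)
}

#' Simulate a full cohort
#'
#' Draws per-subject expectation weights according to the cohort spec, runs
#' every subject through a freshly shuffled copy of the experiment design and
#' concatenates the records. Subjects are mutually independent; the whole
#' cohort is reproducible from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @param grid An [intensity_grid()].
#'
#' @return A list with `ratings` (all trial records) and `truth` (one row per
#'   subject: `subject_id`, `w`, `sigma_prior`, `sd_nociceptor`,
#'   `sigma_rating`, `seed`).
#' @examples
#' coh <- simulate_cohort(cohort_spec(4, 2, seed = 99))
#' nrow(coh$ratings) # 4 x 64
#' @export
simulate_cohort <- function(spec, grid = intensity_grid()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ws <- if (is.character(spec$w)) {
    withr::with_seed(spec$seed, stats::runif(spec$n_subjects))
  } else {
    rep_len(spec$w, spec$n_subjects)
  }
  sims <- purrr::map(seq_len(spec$n_subjects), function(i) {
    params <- subject_params(
      w = ws[i], sigma_prior = spec$sigma_prior,
      sd_nociceptor = spec$sd_nociceptor, sigma_rating = spec$sigma_rating,
      s_low = spec$s_low, s_high = spec$s_high
    )
    sseed <- child_seed(spec$seed, i)
    design <- make_design(spec$experiment, seed = sseed)
    simulate_subject(params, design, seed = sseed, grid = grid,
                     subject_id = i)
  })
  truth <- tibble::tibble(
    subject_id = seq_len(spec$n_subjects),
    w = ws,
    sigma_prior = spec$sigma_prior,
    sd_nociceptor = spec$sd_nociceptor,
    sigma_rating = spec$sigma_rating,
    seed = child_seed(spec$seed, seq_len(spec$n_subjects))
  )
  list(ratings = dplyr::bind_rows(sims), truth = truth)
}
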