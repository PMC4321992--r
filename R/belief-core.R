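# Core inference machinery of the full Bayesian decision (fBD) model ----------
#
# Chain: conditioned prior over the tissue effect E -> Gaussian nociceptor
# likelihood Pr(N|E) -> posterior Pr(E|N,C) -> MAP decision E-hat -> rating
# distribution Pr(R|S,C) marginalized over the nociceptor signal.

#' Prior over the stimulus effect after conditioning (no cue)
#'
#' Mixture learned during the conditioning blocks: two Gaussian components at
#' the low and high stimulus anchors with weight `w/2` each, plus a uniform
#' component with weight `1 - w`. At `w = 0` no conditioning took place and
#' the prior is flat.
#'
#' @param params A [subject_params()] object.
#' @param grid An [intensity_grid()].
#' @param w Expectation weight; defaults to `params$w`.
#'
#' @return A [belief()] distribution over the grid.
#' @examples
#' build_prior(subject_params(w = 0.9), intensity_grid())
#' @export
build_prior <- function(params, grid, w = params$w) {
  stopifnot(inherits(params, "subject_params"), inherits(grid, "intensity_grid"))
  check_w(w)
  mass <- w / 2 * discretize_gaussian(grid, params$s_low, params$sigma_prior) +
    w / 2 * discretize_gaussian(grid, params$s_high, params$sigma_prior) +
    (1 - w) * uniform_mass(grid)
  belief(grid, mass)
}

#' Cue-conditioned prior Pr(E|C)
#'
#' The cue disambiguates which conditioned stimulus is expected: it moves the
#' whole conditioned weight `w` onto its associated component (low anchor for
#' the green/treatment cue, high anchor for the red/no-treatment cue) while
#' the uniform floor keeps weight `1 - w`. With no cue the prior reduces to
#' [build_prior()]. Marginalizing over equiprobable cues recovers the
#' two-component conditioning mixture.
#'
#' @inheritParams build_prior
#' @param cue One of `"red"`, `"green"`, `"none"`.
#'
#' @return A [belief()] distribution over the grid.
#' @export
build_cue_prior <- function(cue, params, grid, w = params$w) {
  check_cue(cue)
  check_w(w)
  if (cue == "none") return(build_prior(params, grid, w = w))
  anchor <- if (cue == "green") params$s_low else params$s_high
  mass <- w * discretize_gaussian(grid, anchor, params$sigma_prior) +
    (1 - w) * uniform_mass(grid)
  belief(grid, mass)
}

#' Nociceptor likelihood kernel Pr(N|E)
#'
#' For every tissue-effect grid value e, the distribution of the evoked
#' nociceptor signal is Gaussian with mean `mu(e)` (identity by default: one
#' common intensity axis) and fixed standard deviation. The kernel stores the
#' raw Gaussian densities and, row-wise, the discretized distribution over
#' the signal grid renormalized to sum to one.
#'
#' @param grid An [intensity_grid()].
#' @param sd Standard deviation of the signal given the effect, in intensity
#'   units (see [subject_params()]).
#' @param mu Mean map from effect to expected signal; defaults to identity.
#'
#' @return An object of class `likelihood_kernel` with elements `grid`, `sd`,
#'   `density` (raw Gaussian density, effects in rows, signals in columns) and
#'   `rows` (row-renormalized probability masses).
#' @export
likelihood_kernel <- function(grid, sd, mu = identity) {
  stopifnot(inherits(grid, "intensity_grid"))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("`sd` must be a positive scalar", call. = FALSE)
  }
  pts <- grid_points(grid)
  mus <- mu(pts)
  dens <- outer(mus, pts, function(m, n) stats::dnorm(n, m, sd))
  rows <- dens / pmax(rowSums(dens), .Machine$double.xmin)
  structure(list(grid = grid, sd = sd, mu = mu, density = dens, rows = rows),
            class = "likelihood_kernel")
}

#' @export
print.likelihood_kernel <- function(x, ...) {
  cat(sprintf("<likelihood_kernel> %d x %d, sd = %g\n",
              nrow(x$density), ncol(x$density), x$sd))
  invisible(x)
}

# Kernel cache: fitting loops reuse the same (grid, sd) kernel thousands of
# times; the 201x201 density matrix is worth keeping around.
.kernel_cache <- new.env(parent = emptyenv())

get_kernel <- function(grid, sd) {
  key <- sprintf("%.10g_%.10g_%.10g_%.10g", grid$lo, grid$hi, grid$step, sd)
  k <- .kernel_cache[[key]]
  if (is.null(k)) {
    k <- likelihood_kernel(grid, sd)
    .kernel_cache[[key]] <- k
  }
  k
}

#' Posterior over the stimulus effect given a nociceptor signal
#'
#' Bayes' rule on the grid: the prior mass is multiplied point-wise by the
#' Gaussian likelihood of the observed signal `n` (evaluated as an
#' untruncated density in `n`, so a signal just outside the grid is still
#' meaningful) and renormalized.
#'
#' @param prior A [belief()] distribution (typically a cue-conditioned prior).
#' @param kernel A [likelihood_kernel()] on the same grid.
#' @param n Observed nociceptor signal (continuous; need not be a grid point).
#'
#' @return A [belief()] posterior distribution.
#' @examples
#' g <- intensity_grid()
#' p <- subject_params(w = 0.9)
#' post <- posterior(build_cue_prior("green", p, g), likelihood_kernel(g, 20), 80)
#' map_estimate(post)
#' @export
posterior <- function(prior, kernel, n) {
  stopifnot(inherits(prior, "belief_dist"), inherits(kernel, "likelihood_kernel"))
  if (!same_grid(prior$grid, kernel$grid)) {
    stop("prior and kernel must share the same grid", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n)) {
    stop("`n` must be a finite scalar", call. = FALSE)
  }
  pts <- grid_points(prior$grid)
  loglik <- stats::dnorm(n, kernel$mu(pts), kernel$sd, log = TRUE)
  # degenerate when every effect carrying prior mass sits further than 8 s.d.
  # from the observation (possible at w = 1, where the uniform floor is gone):
  # raise rather than return numeric dust
  supported <- prior$mass > 0
  if (!any(supported) ||
      max(loglik[supported]) < stats::dnorm(8 * kernel$sd, 0, kernel$sd,
                                            log = TRUE)) {
    stop("degenerate posterior: the observation lies more than 8 s.d. from ",
         "every effect carrying prior mass", call. = FALSE)
  }
  logpost <- log(prior$mass) + loglik
  belief(prior$grid, exp(logpost - max(logpost)))
}

#' Maximum a posteriori decision
#'
#' The decision stage under a uniform cost function: the perceived intensity
#' is the grid point with maximal posterior mass. Exact ties are broken
#' deterministically toward the lower intensity.
#'
#' @param post A [belief()] distribution.
#' @return The grid intensity with maximal mass.
#' @export
map_estimate <- function(post) {
  stopifnot(inherits(post, "belief_dist"))
  grid_points(post$grid)[which.max(post$mass)]
}

# Decision map: MAP estimate for every signal value on the grid, for a given
# cue-conditioned prior. Columns of (prior * density) are posteriors up to
# normalization, which which.max does not need. Returns grid indices.
# A zero column means the observation is impossible under the prior support
# (only reachable at w = 1); flagged with NA.
decision_map_idx <- function(prior_mass, kernel) {
  m <- prior_mass * kernel$density
  idx <- max.col(t(m), ties.method = "first")
  dead <- colSums(m) <= 0
  if (any(dead)) idx[dead] <- NA_integer_
  idx
}

#' Predicted rating distribution Pr(R|S,C)
#'
#' Marginalizes the full generative chain over the nociceptor signal: each
#' grid signal value n is weighted by the discretized Pr(N|S) distribution,
#' mapped to the MAP percept E-hat(n, cue), and contributes a Gaussian
#' rating-coding component N(E-hat, sigma_rating). Components are accumulated
#' unnormalized and the resulting mixture is renormalized once on the grid
#' (a VAS score cannot leave the scale).
#'
#' @param s Stimulus intensity within the grid range.
#' @param cue One of `"red"`, `"green"`, `"none"`.
#' @param params A [subject_params()] object.
#' @param grid An [intensity_grid()].
#' @param w Expectation weight; defaults to `params$w`.
#'
#' @return A [belief()] distribution over ratings.
#' @examples
#' rd <- rating_distribution(50, "none", subject_params(w = 0.9), intensity_grid())
#' belief_modes(rd) # bimodal after strong conditioning
#' @export
rating_distribution <- function(s, cue, params, grid, w = params$w) {
  stopifnot(inherits(params, "subject_params"), inherits(grid, "intensity_grid"))
  if (!is.numeric(s) || length(s) != 1L || s < grid$lo || s > grid$hi) {
    stop("`s` must be a stimulus intensity within the grid range", call. = FALSE)
  }
  kernel <- get_kernel(grid, params$sd_nociceptor)
  prior <- build_cue_prior(cue, params, grid, w = w)
  idx <- decision_map_idx(prior$mass, kernel)
  wts <- discretize_gaussian(grid, s, params$sd_nociceptor)
  if (anyNA(idx) && any(wts[is.na(idx)] > 1e-12)) {
    stop("degenerate posterior: at w = 1 some reachable nociceptor signals ",
         "have zero likelihood under both prior components", call. = FALSE)
  }
  keep <- !is.na(idx)
  mass <- rating_mixture(idx[keep], wts[keep], params$sigma_rating, grid)
  belief(grid, mass)
}

# Accumulate sum_k weight_k * N(points[idx_k], sr) over the grid, unnormalized.
rating_mixture <- function(idx, wts, sr, grid) {
  pts <- grid_points(grid)
  agg <- rowsum(wts, idx)                    # total weight per unique E-hat
  u <- pts[as.integer(rownames(agg))]
  dens <- outer(u, pts, function(m, r) stats::dnorm(r, m, sr))
  as.numeric(crossprod(agg, dens))
}

#' Prediction surface Pr(R|S) over all stimulus intensities
#'
#' One predicted rating distribution per stimulus grid point, for a fixed cue
#' condition, together with the most-probable-rating ridge (the argmax of
#' each row). Before conditioning (`w = 0`) the ridge is the diagonal R = S;
#' after strong conditioning it develops plateaus at the conditioned anchors
#' with an abrupt jump in between.
#'
#' @inheritParams rating_distribution
#'
#' @return An object of class `fbd_surface`: list with `surface` (matrix,
#'   stimulus rows x rating columns, each row a normalized pmf), `ridge`
#'   (tibble with columns `stimulus`, `map_rating`), `grid`, `cue`, `w`.
#' @export
prediction_surface <- function(cue, params, grid, w = params$w) {
  stopifnot(inherits(params, "subject_params"), inherits(grid, "intensity_grid"))
  check_cue(cue)
  kernel <- get_kernel(grid, params$sd_nociceptor)
  prior <- build_cue_prior(cue, params, grid, w = w)
  idx <- decision_map_idx(prior$mass, kernel)
  pts <- grid_points(grid)
  keep <- !is.na(idx)

  # shared machinery across stimuli: weight-per-E-hat depends on s only
  # through the Pr(N|S) row; rating components are fixed.
  agg_index <- match(idx[keep], sort(unique(idx[keep])))
  u <- pts[sort(unique(idx[keep]))]
  comp <- outer(u, pts, function(m, r) stats::dnorm(r, m, params$sigma_rating))

  W <- kernel$rows[, keep, drop = FALSE]     # Pr(N = n | S = s) weights
  if (any(!keep)) W <- W / pmax(rowSums(W), .Machine$double.xmin)
  G <- rowsum(t(W), agg_index)               # unique-E-hat weight per stimulus
  surf <- t(G) %*% comp
  surf <- surf / rowSums(surf)
  rownames(surf) <- colnames(surf) <- NULL

  ridge <- tibble::tibble(
    stimulus = pts,
    map_rating = pts[max.col(surf, ties.method = "first")]
  )
  structure(list(surface = surf, ridge = ridge, grid = grid, cue = cue, w = w),
            class = "fbd_surface")
}

#' @export
print.fbd_surface <- function(x, ...) {
  cat(sprintf("<fbd_surface> cue = %s, w = %.2f, %d stimuli x %d ratings\n",
              x$cue, x$w, nrow(x$surface), ncol(x$surface)))
  invisible(x)
}

#' @export
as_tibble.fbd_surface <- function(x, ...) {
  pts <- grid_points(x$grid)
  tidyr::expand_grid(stimulus = pts, rating = pts) |>
    dplyr::mutate(mass = as.vector(t(x$surface)))
}
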