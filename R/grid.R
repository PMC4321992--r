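# Intensity grid and belief distributions -------------------------------------
#
# Every latent variable of the model (tissue effect E, nociceptor signal N,
# stimulus S, rating R) lives on one common, discretized intensity axis in
# arbitrary 0-100 units. A belief distribution is a normalized probability
# mass over that axis.

#' Discretized intensity axis
#'
#' Builds the common 0-100 (arbitrary units) axis on which stimulus effect,
#' nociceptor signal, stimulus intensity and pain rating are all represented.
#'
#' @param lo,hi Axis end points; `lo < hi`.
#' @param step Grid spacing; `(hi - lo)` must be an integer multiple of `step`.
#'
#' @return An object of class `intensity_grid` with elements `lo`, `hi`,
#'   `step` and the ordered point vector `points`.
#' @examples
#' g <- intensity_grid()
#' length(grid_points(g)) # 201
#' @export
intensity_grid <- function(lo = 0, hi = 100, step = 0.5) {
  if (!is.numeric(lo) || !is.numeric(hi) || !is.numeric(step) ||
      length(lo) != 1L || length(hi) != 1L || length(step) != 1L) {
    stop("`lo`, `hi` and `step` must be scalar numerics", call. = FALSE)
  }
  if (!(lo < hi)) stop("`lo` must be smaller than `hi`", call. = FALSE)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  n_span <- (hi - lo) / step
  if (abs(n_span - round(n_span)) > 1e-8) {
    stop("(hi - lo) must be an integer multiple of `step`", call. = FALSE)
  }
  structure(
    list(lo = lo, hi = hi, step = step,
         points = lo + step * seq.int(0L, round(n_span))),
    class = "intensity_grid"
  )
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat(sprintf("<intensity_grid> [%g, %g] step %g (%d points)\n",
              x$lo, x$hi, x$step, length(x$points)))
  invisible(x)
}

#' Grid points of an intensity grid
#' @param grid An [intensity_grid()].
#' @return Numeric vector of ordered grid points.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "intensity_grid"))
  grid$points
}

n_points <- function(grid) length(grid$points)

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lo, b$lo)) && isTRUE(all.equal(a$hi, b$hi)) &&
    isTRUE(all.equal(a$step, b$step))
}

# index of the grid point nearest to x (x clamped into range)
nearest_index <- function(grid, x) {
  i <- round((pmin(pmax(x, grid$lo), grid$hi) - grid$lo) / grid$step) + 1L
  pmin(pmax(i, 1L), n_points(grid))
}

#' Belief distribution over an intensity grid
#'
#' A normalized probability mass function over the grid points; the container
#' for priors Pr(E), cue-conditioned priors Pr(E|C), posteriors Pr(E|N,C) and
#' predicted rating distributions Pr(R|S,C). The normalization constant of
#' Bayes' rule is absorbed here: mass always sums to one.
#'
#' @param grid An [intensity_grid()].
#' @param mass Non-negative weights, one per grid point; renormalized to sum
#'   to one.
#'
#' @return An object of class `belief_dist` with elements `grid` and `mass`.
#' @export
belief <- function(grid, mass) {
  stopifnot(inherits(grid, "intensity_grid"))
  if (length(mass) != n_points(grid)) {
    stop("`mass` must have one weight per grid point", call. = FALSE)
  }
  if (anyNA(mass) || any(mass < 0)) {
    stop("`mass` must be non-negative and free of NA", call. = FALSE)
  }
  tot <- sum(mass)
  if (!is.finite(tot) || tot <= 0) {
    stop("`mass` must have positive, finite total weight", call. = FALSE)
  }
  structure(list(grid = grid, mass = mass / tot), class = "belief_dist")
}

#' @export
print.belief_dist <- function(x, ...) {
  cat(sprintf("<belief_dist> on [%g, %g] step %g; mean %.2f, mode %g\n",
              x$grid$lo, x$grid$hi, x$grid$step,
              belief_mean(x), map_estimate(x)))
  invisible(x)
}

#' @export
as_tibble.belief_dist <- function(x, ...) {
  tibble::tibble(intensity = grid_points(x$grid), mass = x$mass)
}

#' Mean of a belief distribution
#' @param bd A [belief()] distribution.
#' @return Scalar expectation over the grid.
#' @export
belief_mean <- function(bd) {
  stopifnot(inherits(bd, "belief_dist"))
  sum(grid_points(bd$grid) * bd$mass)
}

#' Variance of a belief distribution
#' @param bd A [belief()] distribution.
#' @return Scalar variance over the grid.
#' @export
belief_var <- function(bd) {
  stopifnot(inherits(bd, "belief_dist"))
  m <- belief_mean(bd)
  sum((grid_points(bd$grid) - m)^2 * bd$mass)
}

#' Count the local maxima of a belief distribution
#'
#' A grid point is a local maximum when its mass strictly exceeds both
#' neighbours (end points compare against their single neighbour). Used for
#' the unimodal-vs-bimodal character of predicted rating distributions.
#'
#' @param bd A [belief()] distribution.
#' @param tol Strictness tolerance guarding against floating-point plateaus.
#' @return Integer number of local maxima.
#' @export
belief_modes <- function(bd, tol = 1e-12) {
  p <- bd$mass
  n <- length(p)
  left <- c(-Inf, p[-n])
  right <- c(p[-1], -Inf)
  sum(p > left + tol & p > right + tol)
}

# Discretized (truncated, renormalized) Gaussian pmf over the grid.
# Computed in log space so far-off-grid means still normalize cleanly.
discretize_gaussian <- function(grid, mean, sd) {
  if (sd <= 0) stop("Gaussian s.d. must be positive", call. = FALSE)
  ld <- stats::dnorm(grid$points, mean, sd, log = TRUE)
  w <- exp(ld - max(ld))
  w / sum(w)
}

# Uniform pmf over the grid ("anything is possible" component).
uniform_mass <- function(grid) rep(1 / n_points(grid), n_points(grid))
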