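# Model comparison, clustering and inferential tests --------------------------

#' Posterior model probabilities on held-out ratings
#'
#' Scores a set of candidate models, each represented by its normalized
#' predictive rating distribution, against held-out ratings. With equal model
#' priors the posterior probabilities are proportional to the predictive
#' likelihoods; each model's Bayes factor is taken against the best of the
#' other models (so only the winner has a Bayes factor above one).
#'
#' @param heldout Numeric vector of held-out ratings.
#' @param predictives Named list of [belief()] distributions on a common
#'   grid, one per model.
#'
#' @return A tibble with one row per model: `model`, `loglik`, `posterior`,
#'   `bayes_factor`, `flagged` (TRUE when an observation had zero predictive
#'   density, handled as minimal posterior).
#' @export
model_posteriors <- function(heldout, predictives) {
  stopifnot(is.numeric(heldout), length(heldout) >= 1L,
            is.list(predictives), length(predictives) >= 2L,
            !is.null(names(predictives)),
            all(vapply(predictives, inherits, TRUE, "belief_dist")))
  grid <- predictives[[1]]$grid
  for (p in predictives) stopifnot(same_grid(p$grid, grid))
  if (any(heldout < grid$lo | heldout > grid$hi)) {
    warning("held-out ratings outside the grid range were clamped to the ",
            "boundary", call. = FALSE)
  }
  idx <- nearest_index(grid, heldout)
  scores <- purrr::imap_dfr(predictives, function(p, nm) {
    lp <- log(p$mass[idx] / grid$step)      # pmf -> density on the scale
    tibble::tibble(model = nm, loglik = sum(lp), flagged = any(!is.finite(lp)))
  })
  ll <- scores$loglik
  ll[!is.finite(ll)] <- -Inf
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  bf <- vapply(seq_along(ll), function(i) {
    exp(ll[i] - max(ll[-i]))
  }, numeric(1))
  scores$posterior <- post
  scores$bayes_factor <- bf
  scores[, c("model", "loglik", "posterior", "bayes_factor", "flagged")]
}

#' Two-cluster Hartigan-Wong K-means with separation index
#'
#' Clusters a score vector into two groups with the Hartigan-Wong algorithm,
#' restarted from a fixed set of quantile-pair initializations (deterministic
#' for a given seed), keeping the solution with the smallest within-cluster
#' sum of squares. Reports the distance between cluster centers and the
#' separation index: the between-cluster sum of squares (total SS minus
#' within SS) as a fraction of the total sum of squares.
#'
#' @param scores Numeric vector, `n >= 2`, not all equal.
#' @param seed Integer seed for the (deterministic) restarts.
#'
#' @return An object of class `pain_clusters`: list with `centers` (sorted),
#'   `assignment` (1 = lower-center cluster), `sizes`, `within_ss`,
#'   `total_ss`, `center_distance`, `separation_index`.
#' @examples
#' kmeans2(c(0, 2, 8, 10))$separation_index # 64/68
#' @export
kmeans2 <- function(scores, seed = 1L) {
  stopifnot(is.numeric(scores))
  scores <- as.numeric(scores)
  if (length(scores) < 2L) stop("need at least two scores", call. = FALSE)
  if (max(scores) - min(scores) <= 0) {
    stop("degenerate clustering: all scores are equal", call. = FALSE)
  }
  probs <- list(c(.05, .95), c(.1, .9), c(.2, .8), c(.25, .75), c(.3, .7),
                c(.1, .5), c(.5, .9), c(.2, .6), c(.4, .8), c(1 / 3, 2 / 3))
  best <- NULL
  withr::with_seed(seed, {
    for (pr in probs) {
      ctrs <- unname(stats::quantile(scores, pr))
      if (diff(ctrs) == 0) next
      km <- tryCatch(
        stats::kmeans(scores, centers = matrix(ctrs, ncol = 1),
                      algorithm = "Hartigan-Wong"),
        error = function(e) NULL)
      if (is.null(km) || length(km$size) < 2L || any(km$size == 0)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12) {
        best <- km
      }
    }
  })
  if (is.null(best)) {
    stop("k-means failed to produce a two-cluster solution", call. = FALSE)
  }
  ord <- order(best$centers)
  assignment <- match(best$cluster, ord)
  centers <- as.numeric(best$centers[ord])
  total_ss <- sum((scores - mean(scores))^2)
  within_ss <- best$tot.withinss
  structure(
    list(centers = centers, assignment = assignment,
         sizes = as.integer(table(factor(assignment, levels = 1:2))),
         within_ss = within_ss, total_ss = total_ss,
         center_distance = diff(centers),
         separation_index = (total_ss - within_ss) / total_ss),
    class = "pain_clusters"
  )
}

#' @export
print.pain_clusters <- function(x, ...) {
  cat(sprintf(
    "<pain_clusters> centers %.2f / %.2f (n = %d/%d); distance %.2f; separation %.3f\n",
    x$centers[1], x$centers[2], x$sizes[1], x$sizes[2],
    x$center_distance, x$separation_index))
  invisible(x)
}

#' @export
tidy.pain_clusters <- function(x, ...) {
  tibble::tibble(cluster = 1:2, center = x$centers, size = x$sizes)
}

#' @export
glance.pain_clusters <- function(x, ...) {
  tibble::tibble(center_distance = x$center_distance,
                 separation_index = x$separation_index,
                 within_ss = x$within_ss, total_ss = x$total_ss)
}

#' Bayesian test of bimodality against unimodality
#'
#' Compares two data-built hypotheses for a score vector: a single Gaussian
#' with the overall mean and standard deviation (unimodal) against a mixture
#' of two Gaussians whose means and s.d.s equal those of the two K-means
#' clusters, with mixture weights proportional to the cluster sizes
#' (bimodal). Plug-in likelihoods, equal hypothesis priors; returns the
#' posterior probability of bimodality and the Bayes factor
#' bimodal/unimodal.
#'
#' @param scores Numeric vector, `n >= 4`.
#' @param seed Seed forwarded to [kmeans2()].
#' @param sd_floor Lower bound imposed on any cluster s.d. (degenerate
#'   clusters are regularized to this spread, with a warning).
#'
#' @return A list of class `bimodality_test` with `posterior_prob_bimodal`,
#'   `bayes_factor`, `loglik_bimodal`, `loglik_unimodal`, `clusters` (the
#'   [kmeans2()] result) and `degenerate` (TRUE when a cluster had fewer than
#'   two points or needed the s.d. floor).
#' @export
bimodality_test <- function(scores, seed = 1L, sd_floor = 0.5) {
  stopifnot(is.numeric(scores))
  if (length(scores) < 4L) stop("need at least 4 scores", call. = FALSE)
  km <- kmeans2(scores, seed = seed)
  degenerate <- any(km$sizes < 2L)
  m_all <- mean(scores)
  s_all <- stats::sd(scores)
  ll_uni <- sum(stats::dnorm(scores, m_all, max(s_all, sd_floor), log = TRUE))

  pars <- lapply(1:2, function(k) {
    xs <- scores[km$assignment == k]
    s <- if (length(xs) >= 2L) stats::sd(xs) else 0
    if (!is.finite(s) || s < sd_floor) {
      degenerate <<- TRUE
      s <- sd_floor
    }
    list(m = mean(xs), s = s, pi = length(xs) / length(scores))
  })
  if (degenerate) {
    warning("degenerate cluster spread regularized to the s.d. floor",
            call. = FALSE)
  }
  ll_bi <- sum(log(
    pars[[1]]$pi * stats::dnorm(scores, pars[[1]]$m, pars[[1]]$s) +
      pars[[2]]$pi * stats::dnorm(scores, pars[[2]]$m, pars[[2]]$s)))
  bf <- exp(ll_bi - ll_uni)
  structure(
    list(posterior_prob_bimodal = 1 / (1 + exp(ll_uni - ll_bi)),
         bayes_factor = bf, loglik_bimodal = ll_bi, loglik_unimodal = ll_uni,
         clusters = km, degenerate = degenerate),
    class = "bimodality_test"
  )
}

#' @export
print.bimodality_test <- function(x, ...) {
  cat(sprintf(
    "<bimodality_test> Pr(bimodal | data) = %.3f; BF = %.3g%s\n",
    x$posterior_prob_bimodal, x$bayes_factor,
    if (x$degenerate) " [degenerate cluster]" else ""))
  invisible(x)
}

#' @export
tidy.bimodality_test <- function(x, ...) {
  tibble::tibble(posterior_prob_bimodal = x$posterior_prob_bimodal,
                 bayes_factor = x$bayes_factor,
                 loglik_bimodal = x$loglik_bimodal,
                 loglik_unimodal = x$loglik_unimodal,
                 degenerate = x$degenerate)
}

#' One-tailed Pearson correlation test
#'
#' Product-moment correlation with a one-tailed P-value for the positive
#' alternative (via the t transform), the convention used throughout the
#' analyses in this package.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-constant.
#' @return List with `r`, `p`, `n`, `statistic` (t), `df`.
#' @export
pearson_one_tailed <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, alternative = "greater", method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       statistic = unname(ct$statistic), df = unname(ct$parameter))
}

#' One-tailed rank tests
#'
#' Wilcoxon signed-rank (paired) or Mann-Whitney rank-sum (unpaired) test
#' with an explicit one-tailed alternative. P-values are exact (full
#' enumeration) for sample sizes up to 10 per group without ties, and use the
#' normal approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples; equal length when `paired = TRUE`.
#' @param paired Signed-rank test on paired differences if TRUE, rank-sum
#'   otherwise.
#' @param alternative `"less"` (H1: a < b) or `"greater"` (H1: a > b).
#'
#' @return List with `statistic`, `p`, `method`, `exact`.
#' @examples
#' rank_tests(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p # 0.05
#' @export
rank_tests <- function(a, b, paired = FALSE, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(a), is.numeric(b))
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired samples must have equal length", call. = FALSE)
    }
    if (all(a == b)) {
      stop("undefined test: all paired differences are zero", call. = FALSE)
    }
  } else if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n_max <- max(length(a), length(b))
  has_ties <- anyDuplicated(c(a, b)) > 0 || (paired && any(a == b))
  use_exact <- n_max <= 10 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, alternative = alternative,
                       exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = wt$method, exact = use_exact)
}
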