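# ggplot2 methods -------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a belief distribution
#'
#' @param object A [belief()] distribution.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.belief_dist <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$intensity, .data$mass)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "intensity (a.u.)", y = "probability mass") +
    ggplot2::theme_minimal()
}

#' Plot a prediction surface with its most-probable-rating ridge
#'
#' Heat map of Pr(R|S) (each stimulus row scaled to a maximum of one, as in
#' the usual presentation of these surfaces) with the argmax ridge overlaid.
#'
#' @param object An `fbd_surface` from [prediction_surface()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fbd_surface <- function(object, ...) {
  pts <- grid_points(object$grid)
  rel <- object$surface / apply(object$surface, 1, max)
  df <- tidyr::expand_grid(stimulus = pts, rating = pts)
  df$relative <- as.vector(t(rel))
  ggplot2::ggplot(df, ggplot2::aes(.data$stimulus, .data$rating)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$relative)) +
    ggplot2::geom_line(data = object$ridge,
                       ggplot2::aes(.data$stimulus, .data$map_rating),
                       colour = "orange", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "relative\nprobability") +
    ggplot2::labs(
      x = "stimulus intensity (a.u.)", y = "pain rating (a.u.)",
      title = sprintf("cue: %s, w = %.2f", object$cue, object$w)) +
    ggplot2::theme_minimal()
}

#' Plot the likelihood profile of an expectation-weight fit
#'
#' One profile log-likelihood curve over the `w` grid per subject, with the
#' fitted maximum marked.
#'
#' @param object An `fbd_w_fit` from [fit_w()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fbd_w_fit <- function(object, ...) {
  df <- purrr::imap_dfr(object$profiles, function(prof, id) {
    tibble::tibble(subject_id = id, w = object$w_grid, loglik = prof)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$w, .data$loglik,
                                   group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(
      data = dplyr::mutate(object$results,
                           subject_id = as.character(.data$subject_id)),
      ggplot2::aes(.data$w_hat, .data$loglik), colour = "red", size = 1) +
    ggplot2::labs(x = "expectation weight w", y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}
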