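# VAS scaling and placebo magnitude -------------------------------------------

#' Scale VAS ratings within subject and block
#'
#' Makes ratings comparable across subjects: each rating is expressed as a
#' percentage of the subject's mean response to the reference high stimuli of
#' the same block. In placebo blocks (all stimuli high, red/green cues) the
#' reference is the mean rating of the high stimuli paired with the red
#' (no-treatment) cue; elsewhere it is the mean rating of all high stimuli in
#' the block. The reference mean maps to 100.
#'
#' @param records Rating records with columns `subject_id`, `block`, `cue`,
#'   `stimulus_level`, `vas_raw`.
#'
#' @return The records with `vas_scaled` filled in.
#' @examples
#' coh <- simulate_cohort(cohort_spec(2, 1, seed = 3))
#' scale_vas(coh$ratings)
#' @export
scale_vas <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "block", "cue", "stimulus_level", "vas_raw")
                %in% names(records)))
  records |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::group_modify(function(df, key) {
      is_placebo <- all(df$stimulus_level == "high") &&
        any(df$cue == "red") && any(df$cue == "green")
      ref <- if (is_placebo) {
        df$vas_raw[df$cue == "red" & df$stimulus_level == "high"]
      } else {
        df$vas_raw[df$stimulus_level == "high"]
      }
      if (length(ref) == 0L || !is.finite(mean(ref)) || mean(ref) <= 0) {
        stop(sprintf(
          "cannot scale subject %s block %s: reference high-stimulus mean is %s",
          key$subject_id, key$block,
          if (length(ref) == 0L) "absent" else "not positive"), call. = FALSE)
      }
      df$vas_scaled <- 100 * df$vas_raw / mean(ref)
      df
    }) |>
    dplyr::ungroup()
}

#' Placebo analgesia magnitude
#'
#' Percent reduction of the rating of high stimuli under the green (placebo)
#' cue relative to the red (overt no-treatment) cue:
#' `100 * (mean(red) - mean(green)) / mean(red)`. Negative values indicate a
#' nocebo-direction effect.
#'
#' @param records Placebo-block records of one subject (high stimuli with red
#'   and green cues). If a `block` column with several blocks is present,
#'   pass only the placebo block.
#' @param value Rating column to use; defaults to `vas_raw` (the magnitude is
#'   identical for jointly rescaled ratings).
#'
#' @return Scalar percent analgesia.
#' @examples
#' df <- tibble::tibble(stimulus_level = "high",
#'                      cue = c("red", "red", "green"),
#'                      vas_raw = c(50, 50, 35))
#' placebo_magnitude(df) # 30
#' @export
placebo_magnitude <- function(records, value = "vas_raw") {
  stopifnot(is.data.frame(records), value %in% names(records))
  high <- dplyr::filter(records, .data$stimulus_level == "high")
  red <- high[[value]][high$cue == "red"]
  green <- high[[value]][high$cue == "green"]
  if (length(red) == 0L || length(green) == 0L) {
    stop("both red-cued and green-cued high-stimulus ratings are required",
         call. = FALSE)
  }
  if (mean(red) == 0) {
    stop("red-cue reference mean is zero; magnitude undefined", call. = FALSE)
  }
  100 * (mean(red) - mean(green)) / mean(red)
}
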