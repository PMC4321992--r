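# Experimental designs --------------------------------------------------------
#
# Two conditioning/placebo protocols:
#  Experiment 1 (placebo only): 3 blocks x 12 stimuli. Blocks 1-2 condition
#    with 6 high+red and 6 low+green trials each; block 3 delivers 12 high
#    stimuli, half red-cued, half green-cued (placebo test).
#  Experiment 2 (no-cue test + placebo): 4 blocks x 16 stimuli. Blocks 1-2
#    condition with 8 high+red and 8 low+green; block 3 delivers 4 high, 4
#    low and 8 intermediate stimuli all with the neutral (none) cue; block 4
#    is the placebo test with 8 high+red and 8 high+green.

#' Build an experiment design
#'
#' Returns the block/trial schedule of one of the two experiments, with trial
#' order shuffled within each block by a seeded permutation.
#'
#' @param experiment 1 or 2.
#' @param seed Integer seed controlling the within-block shuffles.
#'
#' @return A tibble of class `experiment_design` with columns `block`,
#'   `trial`, `cue`, `stimulus_level`, plus an `experiment` attribute.
#' @examples
#' d <- make_design(2, seed = 1)
#' table(d$block, d$cue)
#' @export
make_design <- function(experiment, seed = 1L) {
  if (!experiment %in% c(1, 2)) {
    stop("`experiment` must be 1 or 2", call. = FALSE)
  }
  blocks <- if (experiment == 1) {
    list(
      data.frame(cue = rep(c("red", "green"), each = 6),
                 stimulus_level = rep(c("high", "low"), each = 6)),
      data.frame(cue = rep(c("red", "green"), each = 6),
                 stimulus_level = rep(c("high", "low"), each = 6)),
      data.frame(cue = rep(c("red", "green"), each = 6),
                 stimulus_level = "high")
    )
  } else {
    list(
      data.frame(cue = rep(c("red", "green"), each = 8),
                 stimulus_level = rep(c("high", "low"), each = 8)),
      data.frame(cue = rep(c("red", "green"), each = 8),
                 stimulus_level = rep(c("high", "low"), each = 8)),
      data.frame(cue = "none",
                 stimulus_level = rep(c("high", "low", "mid"), c(4, 4, 8))),
      data.frame(cue = rep(c("red", "green"), each = 8),
                 stimulus_level = "high")
    )
  }
  design <- withr::with_seed(seed, {
    purrr::imap_dfr(blocks, function(b, i) {
      b <- b[sample.int(nrow(b)), , drop = FALSE]
      tibble::tibble(block = i, trial = seq_len(nrow(b)),
                     cue = b$cue, stimulus_level = b$stimulus_level)
    })
  })
  attr(design, "experiment") <- as.integer(experiment)
  class(design) <- c("experiment_design", class(design))
  design
}

# blocks in which the conditioned prior is active (conditioning itself is
# modelled as instantaneous: flat prior during blocks 1-2, full prior after)
post_conditioning_blocks <- function(experiment) {
  if (experiment == 1) 3L else c(3L, 4L)
}

# index of the placebo test block
placebo_block <- function(experiment) {
  if (experiment == 1) 3L else 4L
}
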