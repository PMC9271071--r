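#' Simulate per-trial behavior on a schedule
#'
#' Plants the session's behavioral structure: a sharp high-to-low seeking
#' state switch at `change_point_trial` (a CS+ trial index). Approach on each
#' trial is Bernoulli with the state-dependent probability; approaches go to
#' the cued side with `p_correct_side` (CS+ only); correct approaches end in
#' drinking with `p_drink_given_correct`. CS- trials are approached at the
#' same state-dependent rates (the task does not punish CS- approaches) but
#' never yield access, so they are never correct or drink trials.
#'
#' @param schedule data.frame from [generate_schedule()].
#' @param config the [sim_config()].
#' @param seed integer seed.
#' @return list with `trials` (the schedule plus logical columns `approach`,
#'   `correct`, `drink` and `approach_side`) and `truth` (planted ground
#'   truth: `change_point_trial` and the per-trial flags; the analysis path
#'   never reads it).
#' @export
simulate_behavior <- function(schedule, config, seed = config$seed + 1L) {
  validate_sim_config(config)
  with_seed(seed, {
    tr <- schedule
    n <- nrow(tr)
    cp_trial <- config$change_point_trial
    cp_onset <- tr$cs_onset[tr$cs_type == "plus" & tr$cs_index == cp_trial]
    high <- tr$cs_onset < cp_onset
    # the change-point trial itself is the first low-seeking trial
    p_app <- ifelse(high, config$p_approach_high, config$p_approach_low)
    approach <- runif(n) < p_app
    correct_draw <- runif(n) < config$p_correct_side
    is_plus <- tr$cs_type == "plus"
    correct <- approach & is_plus & correct_draw
    drink <- correct & (runif(n) < config$p_drink_given_correct)
    approach_side <- rep(NA_character_, n)
    other <- function(s) ifelse(s == "left", "right", "left")
    approach_side[approach & is_plus & correct_draw] <-
      tr$side[approach & is_plus & correct_draw]
    approach_side[approach & is_plus & !correct_draw] <-
      other(tr$side[approach & is_plus & !correct_draw])
    n_minus_app <- sum(approach & !is_plus)
    approach_side[approach & !is_plus] <-
      sample(c("left", "right"), n_minus_app, replace = TRUE)
    tr$approach <- approach
    tr$correct <- correct
    tr$drink <- drink
    tr$approach_side <- approach_side
    truth <- list(change_point_trial = cp_trial,
                  approach = approach, correct = correct, drink = drink)
    list(trials = tr, truth = truth)
  })
}
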