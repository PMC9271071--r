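#' Configuration for a synthetic cued-access (2CAP) session
#'
#' Bundles every tunable of the synthetic session generator: the trial
#' schedule (48 CS+ and 48 CS- trials by default, pseudorandom intertrial
#' intervals from the standard set), behavioral state parameters (a sharp
#' high-to-low approach-state switch at `change_point_trial`), snout-tracking
#' kinematics, and the log-linear Poisson population rate model whose four
#' latent signals (seeking state, cue, approach ramp, drink response) carry
#' group-specific gains.
#'
#' @param n_cs_plus,n_cs_minus trial counts per type (default 48 each).
#' @param iti_set allowed intertrial intervals in seconds, measured from the
#'   end of one CS+ trial (cue + access) to the next CS+ onset.
#' @param cs_duration cue duration, s (default 4).
#' @param access_duration fluid-access duration after the CS+, s (default 8).
#' @param cs_minus_exclusion minimum separation of a CS- onset (and its end)
#'   from flanking CS+ trial boundaries, s (default 3).
#' @param alternation_p probability that consecutive trials differ in CS type
#'   (default 0.6, the pseudorandom alternation bias of the task).
#' @param change_point_trial 1-based CS+ trial index of the first low-seeking
#'   trial (default 25, splitting 48 CS+ trials into 24/24).
#' @param p_approach_high,p_approach_low per-trial approach probabilities in
#'   the high- and low-seeking states (defaults 0.9 / 0.2).
#' @param p_correct_side probability an approach goes to the cued sipper
#'   (default 0.9).
#' @param p_drink_given_correct probability a correct approach ends in
#'   drinking (default 0.95; correct approaches almost always yield at least
#'   one lick).
#' @param arena_width,arena_height arena size in tracking pixels.
#' @param sipper_left,sipper_right sipper (x, y) coordinates in pixels.
#' @param tracking_rate snout-tracking frame rate, Hz (default 30).
#' @param tracking_noise_sd Gaussian positional jitter, px (default 2).
#' @param session_lead_in quiet period before the first CS+ onset, s.
#' @param n_neurons units simulated per group label.
#' @param baseline_rate baseline firing rate, Hz (default 5).
#' @param signal_gains named list: one entry per group label, each a named
#'   numeric vector with nonnegative gains for `seek`, `cue`, `approach`,
#'   `drink`.
#' @param loading_spread SD of per-neuron loadings around their class mean.
#' @param ei_fraction fraction of units drawn from the narrow-fast
#'   (putative inhibitory) waveform template (default 0.2).
#' @param rate_cap maximum admissible instantaneous rate, Hz (default 200);
#'   the generator refuses configurations whose rates exceed it.
#' @param seed default root seed for the generator.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cs_plus = 48L,
                       n_cs_minus = 48L,
                       iti_set = c(20, 28, 36, 44, 56, 68, 96, 120),
                       cs_duration = 4,
                       access_duration = 8,
                       cs_minus_exclusion = 3,
                       alternation_p = 0.6,
                       change_point_trial = 25L,
                       p_approach_high = 0.9,
                       p_approach_low = 0.2,
                       p_correct_side = 0.9,
                       p_drink_given_correct = 0.95,
                       arena_width = 640,
                       arena_height = 240,
                       sipper_left = c(40, 120),
                       sipper_right = c(600, 120),
                       tracking_rate = 30,
                       tracking_noise_sd = 2,
                       session_lead_in = 30,
                       n_neurons = 250L,
                       baseline_rate = 5,
                       signal_gains = list(
                         grp = c(seek = 1, cue = 1, approach = 1, drink = 1)
                       ),
                       loading_spread = 0.4,
                       ei_fraction = 0.2,
                       rate_cap = 200,
                       seed = 1L) {
  cfg <- list(
    n_cs_plus = as.integer(n_cs_plus), n_cs_minus = as.integer(n_cs_minus),
    iti_set = as.numeric(iti_set), cs_duration = cs_duration,
    access_duration = access_duration,
    cs_minus_exclusion = cs_minus_exclusion,
    alternation_p = alternation_p,
    change_point_trial = as.integer(change_point_trial),
    p_approach_high = p_approach_high, p_approach_low = p_approach_low,
    p_correct_side = p_correct_side,
    p_drink_given_correct = p_drink_given_correct,
    arena_width = arena_width, arena_height = arena_height,
    sipper_left = sipper_left, sipper_right = sipper_right,
    tracking_rate = tracking_rate, tracking_noise_sd = tracking_noise_sd,
    session_lead_in = session_lead_in,
    n_neurons = as.integer(n_neurons), baseline_rate = baseline_rate,
    signal_gains = signal_gains, loading_spread = loading_spread,
    ei_fraction = ei_fraction, rate_cap = rate_cap, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a synthetic-session configuration
#' @param config a `sim_config` list.
#' @return the config, invisibly; stops on violation.
#' @export
validate_sim_config <- function(config) {
  probs <- c(config$alternation_p, config$p_approach_high,
             config$p_approach_low, config$p_correct_side,
             config$p_drink_given_correct, config$ei_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config: all probabilities must lie in [0, 1]")
  }
  durs <- c(config$iti_set, config$cs_duration, config$access_duration,
            config$cs_minus_exclusion, config$session_lead_in)
  if (any(durs <= 0)) stop("sim_config: all durations must be positive")
  if (config$change_point_trial < 1L ||
      config$change_point_trial > config$n_cs_plus) {
    stop("sim_config: change_point_trial must lie in [1, n_cs_plus]")
  }
  if (config$n_cs_plus < 1L) stop("sim_config: need at least one CS+ trial")
  for (g in names(config$signal_gains)) {
    gv <- config$signal_gains[[g]]
    need <- c("seek", "cue", "approach", "drink")
    if (!all(need %in% names(gv))) {
      stop("sim_config: signal_gains[['", g, "']] must name ",
           paste(need, collapse = ", "))
    }
    if (any(gv < 0)) stop("sim_config: gains must be nonnegative")
  }
  if (config$baseline_rate <= 0) stop("sim_config: baseline_rate must be > 0")
  if (config$tracking_noise_sd * 6 > min(config$arena_width,
                                         config$arena_height)) {
    stop("sim_config: arena too small for the tracking noise amplitude")
  }
  invisible(config)
}
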