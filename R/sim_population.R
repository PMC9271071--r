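# Inhomogeneous-Poisson population simulator with four planted latent
# signals: seeking state, cue response, approach ramp, drink response.

alpha_kernel <- function(tau, tc) {
  k <- (tau / tc) * exp(1 - tau / tc)
  k[tau < 0] <- 0
  k
}

# latent signal time courses on a fine grid (absolute session time)
latent_signals <- function(trials, truth, config, grid) {
  g <- matrix(0, 4, length(grid),
              dimnames = list(c("seek", "cue", "approach", "drink"), NULL))
  cs_dur <- config$cs_duration
  plus <- trials$cs_type == "plus"
  for (i in which(plus)) {
    onset <- trials$cs_onset[i]
    if (trials$cs_index[i] < config$change_point_trial) {
      idx <- grid >= onset - 6 & grid < onset
      g["seek", idx] <- 1
    }
    # cue kernel spans the cue presentation (fast rise, slow decay), as
    # prefrontal cue responses persist through the CS
    tau <- grid - onset
    idx <- tau >= 0 & tau <= cs_dur + 2
    g["cue", idx] <- pmax(g["cue", idx], alpha_kernel(tau[idx], 1.2))
  }
  for (i in seq_len(nrow(trials))) {
    if (!isTRUE(trials$approach[i]) || is.na(truth$approach_init[i])) next
    t_ai <- trials$cs_onset[i] + truth$approach_init[i]
    ramp_idx <- grid >= t_ai - 3 & grid < t_ai
    g["approach", ramp_idx] <- pmax(g["approach", ramp_idx],
                                    (grid[ramp_idx] - (t_ai - 3)) / 3)
    dec_idx <- grid >= t_ai & grid < t_ai + 0.5
    g["approach", dec_idx] <- pmax(g["approach", dec_idx],
                                   1 - (grid[dec_idx] - t_ai) / 0.5)
    if (isTRUE(trials$drink[i]) && !is.na(truth$drink_time[i])) {
      t_d <- trials$cs_onset[i] + truth$drink_time[i]
      tau <- grid - t_d
      idx <- tau >= 0 & tau <= 3
      g["drink", idx] <- pmax(g["drink", idx], alpha_kernel(tau[idx], 0.5))
    }
  }
  g
}

# two-class mean-waveform templates (narrow-fast vs broad-slow rise from the
# depolarization trough), 64 samples at 30 kHz
waveform_template <- function(class, n_samples = 64L) {
  s <- seq_len(n_samples)
  if (class == "inhibitory") {
    -exp(-(s - 20)^2 / (2 * 3^2)) + 0.35 * exp(-(s - 28)^2 / (2 * 4^2))
  } else {
    -exp(-(s - 20)^2 / (2 * 5^2)) + 0.35 * exp(-(s - 42)^2 / (2 * 10^2))
  }
}

#' Simulate a spiking population with planted decision signals
#'
#' Each unit's instantaneous rate follows the log-linear model
#' `lambda_i(t) = exp(log(baseline) + sum_s L_is * gain[group, s] * g_s(t))`
#' where the four latent signals are: `seek`, a pre-CS offset active only on
#' pre-change-point CS+ trials; `cue`, a transient kernel after CS+ onset;
#' `approach`, a 3-s ramp up to the true approach initiation; and `drink`, a
#' transient after the true drink time. Spikes are drawn as an inhomogeneous
#' Poisson process (10 ms rate resolution, continuous spike times). Each unit
#' also receives a mean waveform from a narrow-fast (putative inhibitory) or
#' broad-slow (putative excitatory) template with noise.
#'
#' @param trials trial table with behavior flags.
#' @param truth tracking ground truth (from [simulate_tracking()]): per-trial
#'   `approach_init` and `drink_time`.
#' @param config the [sim_config()]; `signal_gains` defines the groups.
#' @param seed integer seed.
#' @param duration session duration, s (default: past the last trial).
#' @return list with `spikes` (data.frame `unit_id`, `spike_time`), `units`
#'   (data.frame `unit_id`, `group`), `waveforms` (units x samples matrix,
#'   rownames = unit ids; attr `sample_rate` = 30000), and `truth`
#'   (per-unit true class and loading matrix).
#' @export
simulate_population <- function(trials, truth, config,
                                seed = config$seed + 3L,
                                duration = NULL) {
  validate_sim_config(config)
  with_seed(seed, {
    dt <- 0.01
    duration <- duration %||%
      (max(trials$cs_onset) + config$cs_duration + config$access_duration + 20)
    grid <- seq(0, duration - dt, by = dt)
    G <- latent_signals(trials, truth, config, grid)

    groups <- names(config$signal_gains)
    n_per <- config$n_neurons
    n_tot <- n_per * length(groups)
    unit_group <- rep(groups, each = n_per)
    unit_id <- paste0(unit_group, "_", sprintf("%04d", sequence(rep(n_per, length(groups)))))
    class_true <- ifelse(runif(n_tot) < config$ei_fraction,
                         "inhibitory", "excitatory")
    mu_load <- ifelse(class_true == "inhibitory", 0.25, 0.5)
    L <- matrix(rnorm(n_tot * 4, mean = mu_load, sd = config$loading_spread),
                n_tot, 4, dimnames = list(unit_id, rownames(G)))
    gain_mat <- t(vapply(unit_group, function(g) {
      config$signal_gains[[g]][c("seek", "cue", "approach", "drink")]
    }, numeric(4)))
    W <- L * gain_mat # effective per-unit signal weights

    chunk <- 20000L
    n_bins <- length(grid)
    sp_unit <- vector("list", ceiling(n_bins / chunk))
    sp_time <- vector("list", ceiling(n_bins / chunk))
    ci <- 0L
    for (b0 in seq(1L, n_bins, by = chunk)) {
      b1 <- min(b0 + chunk - 1L, n_bins)
      lam <- exp(log(config$baseline_rate) + W %*% G[, b0:b1, drop = FALSE])
      if (any(lam > config$rate_cap)) {
        stop("simulate_population: realized instantaneous rate ",
             round(max(lam), 1), " Hz exceeds rate_cap = ",
             config$rate_cap, " Hz; reduce gains or loading_spread")
      }
      cnt <- matrix(rpois(length(lam), lam * dt), nrow = n_tot)
      nz <- which(cnt > 0L, arr.ind = TRUE)
      if (nrow(nz) > 0L) {
        k <- cnt[nz]
        ui <- rep(nz[, 1], k)
        tb <- grid[b0 - 1L + rep(nz[, 2], k)]
        ci <- ci + 1L
        sp_unit[[ci]] <- ui
        sp_time[[ci]] <- tb + runif(length(tb), 0, dt)
      }
    }
    ui <- unlist(sp_unit)
    st <- unlist(sp_time)
    ord <- order(ui, st)
    spikes <- data.frame(unit_id = unit_id[ui[ord]], spike_time = st[ord],
                         stringsAsFactors = FALSE)

    n_samp <- 64L
    wf <- matrix(NA_real_, n_tot, n_samp, dimnames = list(unit_id, NULL))
    amp <- runif(n_tot, 50, 200)
    for (i in seq_len(n_tot)) {
      wf[i, ] <- amp[i] * (waveform_template(class_true[i], n_samp) +
                             rnorm(n_samp, 0, 0.015))
    }
    attr(wf, "sample_rate") <- 30000

    list(
      spikes = spikes,
      units = data.frame(unit_id = unit_id, group = unit_group,
                         stringsAsFactors = FALSE),
      waveforms = wf,
      truth = list(class = setNames(class_true, unit_id), loadings = L)
    )
  })
}
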