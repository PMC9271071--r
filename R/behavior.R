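# Behavioral inference: approach likelihood, approach/drink initiation,
# surrogate event times, phenotype classification, session metrics.

resample_track <- function(tracking, times) {
  list(x = approx(tracking$time, tracking$x, xout = times, rule = 2)$y,
       y = approx(tracking$time, tracking$y, xout = times, rule = 2)$y)
}

#' Trial-by-trial approach likelihood from snout kinematics
#'
#' Estimates, for every trial and 100-ms bin after CS+ onset, the likelihood
#' that the animal is approaching, as the weighted average of the other
#' trials' approach outcomes: `q_i(t) = sum_{j != i} w_ij(t) p_j`. The weights
#' are normalized inverse Euclidean distances between the trials' snout state
#' vectors (x, y, vx, vy) at the matched time bin; the four dimensions are
#' z-scored over all trials and bins before distances so position (px) and
#' velocity (px/s) contribute on a common scale.
#'
#' @param trials trial table (rows define the trials to evaluate; must have
#'   `cs_onset` and logical `approach`).
#' @param tracking data.frame `time`, `x`, `y`.
#' @param window evaluation window in s relative to CS onset (default
#'   `c(0, 12)`: cue plus access).
#' @param bin_width bin width in s (default 0.1).
#' @param eps regularizer added to distances (in z-units) so an exact-zero
#'   distance yields near-total weight without division failure.
#' @param return_weights keep the full trials x trials x bins weight array.
#' @return list with `q` (trials x bins matrix), `t_rel` (bin start times),
#'   `trials` (row indices used) and optionally `weights`.
#' @export
approach_likelihood <- function(trials, tracking, window = c(0, 12),
                                bin_width = 0.1, eps = 1e-6,
                                return_weights = FALSE) {
  n <- nrow(trials)
  if (n < 2L) stop("approach_likelihood: need at least 2 trials")
  t_rel <- seq(window[1], window[2] - bin_width / 2, by = bin_width)
  nb <- length(t_rel)
  Z <- array(NA_real_, c(n, nb, 4))
  for (i in seq_len(n)) {
    pos <- resample_track(tracking, trials$cs_onset[i] + t_rel)
    vx <- c(pos$x[2] - pos$x[1],
            (pos$x[-(1:2)] - pos$x[-((nb - 1):nb)]) / 2,
            pos$x[nb] - pos$x[nb - 1]) / bin_width
    vy <- c(pos$y[2] - pos$y[1],
            (pos$y[-(1:2)] - pos$y[-((nb - 1):nb)]) / 2,
            pos$y[nb] - pos$y[nb - 1]) / bin_width
    Z[i, , ] <- cbind(pos$x, pos$y, vx, vy)
  }
  bad <- apply(Z, 1, function(m) all(is.na(m)))
  if (any(bad)) {
    warning("approach_likelihood: excluding ", sum(bad),
            " trial(s) with all-missing tracking")
  }
  used <- which(!bad)
  Z <- Z[used, , , drop = FALSE]
  m <- length(used)
  for (d in 1:4) {
    v <- Z[, , d]
    Z[, , d] <- (v - mean(v, na.rm = TRUE)) / max(sd(v, na.rm = TRUE), 1e-12)
  }
  p <- as.numeric(trials$approach[used])
  q <- matrix(NA_real_, m, nb)
  W <- if (return_weights) array(NA_real_, c(m, m, nb)) else NULL
  for (t in seq_len(nb)) {
    D <- as.matrix(dist(Z[, t, ]))
    iw <- 1 / (D + eps)
    diag(iw) <- 0
    iw <- iw / rowSums(iw)
    q[, t] <- as.numeric(iw %*% p)
    if (return_weights) W[, , t] <- iw
  }
  out <- list(q = q, t_rel = t_rel, trials = used, p = p,
              bin_width = bin_width)
  if (return_weights) out$weights <- W
  out
}

#' Approach initiation times from the approach likelihood
#'
#' For each approach trial, the approach initiation is the largest-magnitude
#' change point of its approach-likelihood trace `q_i(t)` (same single-split
#' residual-sum-of-squares engine as the session change point). The returned
#' time is the start of the first post-change bin, in s relative to CS onset.
#' Trials with a flat likelihood are flagged (`NA`).
#'
#' @param q result of [approach_likelihood()].
#' @param approach logical vector over `q`'s trials (defaults to the approach
#'   status stored in `q`).
#' @return data.frame `trial` (index into the original trial table),
#'   `approach_init` (s, `NA` when undefined), `magnitude`.
#' @export
detect_approach_initiation <- function(q, approach = q$p > 0) {
  out <- data.frame(trial = q$trials,
                    approach_init = NA_real_, magnitude = NA_real_)
  for (k in which(approach)) {
    cp <- change_point_rss(q$q[k, ])
    if (!is.na(cp$index)) {
      out$approach_init[k] <- q$t_rel[1] + (cp$index - 1) * q$bin_width
      out$magnitude[k] <- cp$magnitude
    }
  }
  out
}

#' Assign surrogate event times to no-event trials
#'
#' Trials without a real event of the requested kind receive a time drawn
#' uniformly with replacement from the session's real event times (relative
#' to CS+ onset), so that event-aligned averages can be formed for both trial
#' types. Real-event trials are untouched.
#'
#' @param trials trial table with `approach_init` and/or `drink_time` columns
#'   (s relative to CS onset, `NA` where absent) and the corresponding flags.
#' @param kind `"approach"` or `"drink"`.
#' @param seed integer seed.
#' @return the trial table with surrogate times filled in and a logical
#'   `<kind>_surrogate` column.
#' @export
assign_surrogate_times <- function(trials, kind = c("approach", "drink"),
                                   seed = 1L) {
  kind <- match.arg(kind)
  col <- if (kind == "approach") "approach_init" else "drink_time"
  real <- !is.na(trials[[col]])
  if (!any(real)) stop("assign_surrogate_times: no real ", kind, " events")
  pool <- trials[[col]][real]
  need <- which(!real)
  with_seed(seed, {
    trials[[col]][need] <- sample(pool, length(need), replace = TRUE)
  })
  trials[[paste0(kind, "_surrogate")]] <- !real
  trials
}

#' Detect drink initiation from tracking
#'
#' The drink time of a trial is the first tracking sample inside the access
#' window whose snout position is within `radius` pixels of the cued (correct)
#' sipper; `NA` if the snout never enters.
#'
#' @param trials trial table with `cs_onset` and `side` (CS+ rows).
#' @param tracking data.frame `time`, `x`, `y`.
#' @param sippers named list with `left` and `right` (x, y) coordinates.
#' @param config a [sim_config()] (for cue/access durations), or a list with
#'   `cs_duration` and `access_duration`.
#' @param radius detection radius in px (default 9, about 1 cm).
#' @return numeric vector of drink times (s relative to CS onset) per row of
#'   `trials`; `NA` for CS- rows and trials that never reach the sipper.
#' @export
detect_drink_initiation <- function(trials, tracking, sippers, config,
                                    radius = 9) {
  if (is.null(sippers$left) || is.null(sippers$right)) {
    stop("detect_drink_initiation: missing sipper coordinates")
  }
  out <- rep(NA_real_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (trials$cs_type[i] != "plus" || is.na(trials$side[i])) next
    a0 <- trials$cs_onset[i] + config$cs_duration
    idx <- which(tracking$time >= a0 &
                   tracking$time <= a0 + config$access_duration)
    if (length(idx) == 0L) next
    sp <- sippers[[trials$side[i]]]
    d <- sqrt((tracking$x[idx] - sp[1])^2 + (tracking$y[idx] - sp[2])^2)
    hit <- which(d <= radius)[1]
    if (!is.na(hit)) out[i] <- tracking$time[idx[hit]] - trials$cs_onset[i]
  }
  out
}

#' CS sensitivity of a session
#'
#' Fraction of all approaches that occurred on CS+ trials; 0.5 is chance,
#' 1.0 is perfect cue discrimination.
#'
#' @param trials trial table with `cs_type` and logical `approach`.
#' @return a fraction in [0, 1].
#' @export
cs_sensitivity <- function(trials) {
  n_app <- sum(trials$approach)
  if (n_app == 0L) stop("cs_sensitivity: undefined, zero approaches")
  sum(trials$approach & trials$cs_type == "plus") / n_app
}

#' Descriptive session metrics from tracking
#'
#' Computes per-trial time at the sipper during access, latency from CS onset
#' to the first sipper-radius entry, the proportion of trials approached, and
#' a per-relative-bin sipper-occupancy likelihood across trials.
#'
#' @param trials trial table (CS+ rows are used for sipper metrics).
#' @param tracking data.frame `time`, `x`, `y`.
#' @param sippers named list of sipper coordinates.
#' @param config list with `cs_duration` and `access_duration`.
#' @param radius occupancy radius in px (default 9).
#' @param occupancy_window relative window for the occupancy series, s.
#' @return list with `time_at_sipper` (s per CS+ trial), `latency` (s per CS+
#'   trial, `NA` if never), `prop_approached`, and `occupancy` (data.frame
#'   `t_rel`, `likelihood`).
#' @export
session_metrics <- function(trials, tracking, sippers, config, radius = 9,
                            occupancy_window = c(-10, 20)) {
  plus <- trials[trials$cs_type == "plus", ]
  dt <- median(diff(tracking$time))
  tas <- lat <- rep(NA_real_, nrow(plus))
  t_rel <- seq(occupancy_window[1], occupancy_window[2], by = 0.1)
  occ <- matrix(0, nrow(plus), length(t_rel))
  for (i in seq_len(nrow(plus))) {
    sp <- sippers[[plus$side[i]]]
    a0 <- plus$cs_onset[i] + config$cs_duration
    idx <- which(tracking$time >= a0 &
                   tracking$time <= a0 + config$access_duration)
    d <- sqrt((tracking$x[idx] - sp[1])^2 + (tracking$y[idx] - sp[2])^2)
    tas[i] <- sum(d <= radius) * dt
    idx2 <- which(tracking$time >= plus$cs_onset[i] &
                    tracking$time <= a0 + config$access_duration)
    d2 <- sqrt((tracking$x[idx2] - sp[1])^2 + (tracking$y[idx2] - sp[2])^2)
    hit <- which(d2 <= radius)[1]
    if (!is.na(hit)) lat[i] <- tracking$time[idx2[hit]] - plus$cs_onset[i]
    pos <- resample_track(tracking, plus$cs_onset[i] + t_rel)
    occ[i, ] <- as.numeric(sqrt((pos$x - sp[1])^2 + (pos$y - sp[2])^2)
                           <= radius)
  }
  list(time_at_sipper = tas, latency = lat,
       prop_approached = mean(trials$approach),
       occupancy = data.frame(t_rel = t_rel, likelihood = colMeans(occ)))
}

#' Reclassify sessions between compulsive and non-compulsive phenotypes
#'
#' Strain sets the default phenotype (P rats compulsive, Wistars
#' non-compulsive). A session is reclassified when its z-scored
#' alcohol+quinine consumption (z computed within strain) crosses +/- 1.4
#' together with the percent decrease in consumption relative to the
#' immediately preceding alcohol session crossing 50%: a P-rat session with
#' z < -1.4 and decrease > 50% becomes non-compulsive; a Wistar session with
#' z > 1.4 and decrease < 50% becomes compulsive.
#'
#' @param sessions data.frame with `strain` (`"P"`/`"Wistar"`),
#'   `consumption_alcohol` and `consumption_quinine` (same units, e.g. g/kg).
#' @param z_threshold z-score threshold (default 1.4).
#' @param decrease_threshold percent-decrease threshold (default 50).
#' @return the input with `z_quinine`, `pct_decrease`, `label`
#'   (`"compulsive"`/`"non-compulsive"`) and logical `reclassified`.
#' @export
classify_session_phenotype <- function(sessions, z_threshold = 1.4,
                                       decrease_threshold = 50) {
  stopifnot(all(sessions$strain %in% c("P", "Wistar")))
  for (s in unique(sessions$strain)) {
    if (sum(sessions$strain == s) < 2L) {
      stop("classify_session_phenotype: strain ", s,
           " has < 2 sessions; z-score undefined")
    }
  }
  z <- ave(sessions$consumption_quinine, sessions$strain,
           FUN = function(v) (v - mean(v)) / sd(v))
  dec <- 100 * (sessions$consumption_alcohol - sessions$consumption_quinine) /
    sessions$consumption_alcohol
  default <- ifelse(sessions$strain == "P", "compulsive", "non-compulsive")
  label <- default
  re_p <- sessions$strain == "P" & z < -z_threshold & dec > decrease_threshold
  re_w <- sessions$strain == "Wistar" & z > z_threshold &
    dec < decrease_threshold
  label[re_p] <- "non-compulsive"
  label[re_w] <- "compulsive"
  sessions$z_quinine <- z
  sessions$pct_decrease <- dec
  sessions$label <- label
  sessions$reclassified <- re_p | re_w
  sessions
}
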