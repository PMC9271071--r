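# Snout-tracking simulation: smooth waypoint paths plus Gaussian jitter.

smoothstep <- function(u) u * u * (3 - 2 * u)

# piecewise smoothstep interpolation of waypoints onto a time grid;
# velocity is continuous (zero at waypoints), positions exact at waypoints
interp_waypoints <- function(wt, wx, wy, grid) {
  n <- length(wt)
  seg <- findInterval(grid, wt, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg >= n] <- n - 1L
  t0 <- wt[seg]; t1 <- wt[seg + 1L]
  u <- (grid - t0) / (t1 - t0)
  u <- pmin(pmax(u, 0), 1)
  s <- smoothstep(u)
  list(x = wx[seg] + s * (wx[seg + 1L] - wx[seg]),
       y = wy[seg] + s * (wy[seg + 1L] - wy[seg]))
}

#' Simulate snout tracking for a session
#'
#' Produces a continuous snout (x, y) trace at `tracking_rate`. On approach
#' trials the snout leaves its mid-arena wander at a latent initiation time —
#' conditioned approach is stereotyped, so latency is a session-level base
#' (uniform in [1, 2] s after CS onset) plus small per-trial jitter — then
#' darts to the chosen sipper along a smoothed sigmoidal path, dwells there
#' (through the access period on drink trials), and returns. On no-approach trials the
#' snout wanders in a central region bounded away from both sippers. Gaussian
#' positional jitter of SD `tracking_noise_sd` px is added to the whole trace.
#' True initiation and sipper-arrival times are recorded as ground truth.
#'
#' @param trials trial table with behavior flags (from [simulate_behavior()]).
#' @param config the [sim_config()].
#' @param seed integer seed.
#' @return list with `tracking` (data.frame `time`, `x`, `y`), `sippers`
#'   (named list of left/right coordinates), and `truth` (per-trial
#'   `approach_init` and `arrival` in s relative to CS onset, NA where
#'   undefined; `drink_time` for correct-approach trials).
#' @export
simulate_tracking <- function(trials, config, seed = config$seed + 2L) {
  with_seed(seed, {
    cs_dur <- config$cs_duration
    acc <- config$access_duration
    w <- config$arena_width; h <- config$arena_height
    sip <- list(left = config$sipper_left, right = config$sipper_right)
    # idle snout positions: each animal stations at a preferred central spot
    # between trials (session-level staging point with per-visit scatter)
    stage <- c(runif(1, 0.4 * w, 0.6 * w), runif(1, 0.35 * h, 0.65 * h))
    central <- function(n = 1L) {
      cbind(pmin(pmax(stage[1] + rnorm(n, 0, 12), 0.05 * w), 0.95 * w),
            pmin(pmax(stage[2] + rnorm(n, 0, 12), 0.05 * h), 0.95 * h))
    }
    # conditioned approach is stereotyped: a session-level latency base with
    # small per-trial jitter, and a ballistic, time-stereotyped dart to the
    # sipper (constant movement time, speed scales with distance)
    travel <- 0.5
    lat0 <- runif(1, 1.0, 2.0)

    ord <- order(trials$cs_onset)
    tr <- trials[ord, ]
    n <- nrow(tr)
    wp_t <- 0; p0 <- central(); wp_x <- p0[1]; wp_y <- p0[2]
    truth_init <- rep(NA_real_, n)
    search_win <- matrix(NA_real_, n, 2) # abs window to locate arrival
    dwell_starts <- numeric(0)           # gaps that must stay at the sipper
    t_cursor <- 0.2
    for (i in seq_len(n)) {
      if (!tr$approach[i]) next
      onset <- tr$cs_onset[i]
      # cursor keeps waypoint times ordered when trials are packed tightly
      start <- max(onset + lat0 + rnorm(1, 0, 0.1), onset + 0.5,
                   t_cursor + 0.2)
      pos <- central()
      target <- sip[[tr$approach_side[i]]]
      arrive <- start + travel
      leave <- if (tr$cs_type[i] == "plus" && tr$correct[i]) {
        onset + cs_dur + acc
      } else {
        arrive + 1.0
      }
      leave <- max(leave, arrive + 0.3)
      back_t <- leave + 1.2
      back <- central()
      wp_t <- c(wp_t, start, arrive, leave, back_t)
      wp_x <- c(wp_x, pos[1], target[1], target[1], back[1])
      wp_y <- c(wp_y, pos[2], target[2], target[2], back[2])
      truth_init[i] <- start - onset
      search_win[i, ] <- c(start, leave)
      dwell_starts <- c(dwell_starts, arrive)
      t_cursor <- back_t
    }
    duration <- max(tr$cs_onset) + cs_dur + acc + 20
    # fill wander waypoints in gaps so no-approach periods stay central
    wp <- data.frame(t = wp_t, x = wp_x, y = wp_y)
    wp <- wp[order(wp$t), ]
    fill_t <- c(); fill_x <- c(); fill_y <- c()
    bounds <- c(wp$t, duration)
    for (k in seq_len(length(bounds) - 1L)) {
      gap <- bounds[k + 1L] - bounds[k]
      if (any(abs(bounds[k] - dwell_starts) < 1e-9)) next # stay at sipper
      if (gap > 4) {
        ts <- seq(bounds[k] + 2, bounds[k + 1L] - 1, by = 3)
        if (length(ts) > 0L) {
          ps <- central(length(ts))
          fill_t <- c(fill_t, ts); fill_x <- c(fill_x, ps[, 1])
          fill_y <- c(fill_y, ps[, 2])
        }
      }
    }
    wp <- rbind(wp, data.frame(t = c(fill_t, duration),
                               x = c(fill_x, central()[1]),
                               y = c(fill_y, central()[2])))
    wp <- wp[order(wp$t), ]
    wp <- wp[c(TRUE, diff(wp$t) > 1e-9), ] # drop duplicate times

    grid <- seq(0, duration, by = 1 / config$tracking_rate)
    path <- interp_waypoints(wp$t, wp$x, wp$y, grid)

    # ground-truth arrivals from the noiseless path
    radius <- 9
    truth_arrival <- rep(NA_real_, n)
    truth_drink <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (!tr$approach[i]) next
      target <- sip[[tr$approach_side[i]]]
      idx <- which(grid >= search_win[i, 1] & grid <= search_win[i, 2])
      d <- sqrt((path$x[idx] - target[1])^2 + (path$y[idx] - target[2])^2)
      hit <- which(d <= radius)[1]
      if (!is.na(hit)) truth_arrival[i] <- grid[idx[hit]] - tr$cs_onset[i]
      if (tr$cs_type[i] == "plus" && tr$correct[i]) {
        a0 <- tr$cs_onset[i] + cs_dur
        idx2 <- which(grid >= a0 & grid <= a0 + acc)
        csip <- sip[[tr$side[i]]]
        d2 <- sqrt((path$x[idx2] - csip[1])^2 + (path$y[idx2] - csip[2])^2)
        hit2 <- which(d2 <= radius)[1]
        if (!is.na(hit2)) truth_drink[i] <- grid[idx2[hit2]] - tr$cs_onset[i]
      }
    }
    x <- path$x + rnorm(length(grid), 0, config$tracking_noise_sd)
    y <- path$y + rnorm(length(grid), 0, config$tracking_noise_sd)
    # restore original trial order for truth vectors
    inv <- order(ord)
    list(
      tracking = data.frame(time = grid, x = x, y = y),
      sippers = sip,
      truth = data.frame(trial = trials$trial,
                         approach_init = truth_init[inv],
                         arrival = truth_arrival[inv],
                         drink_time = truth_drink[inv])
    )
  })
}
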