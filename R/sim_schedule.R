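# Trial-schedule generation for synthetic 2CAP sessions.

# Draw a CS-type sequence with the task's pseudorandom alternation bias:
# at each step the next trial differs in type with probability alternation_p,
# conditioned (by rejection) on exact per-type counts.
draw_type_sequence <- function(n_plus, n_minus, p_alt, max_tries = 5000L) {
  n <- n_plus + n_minus
  for (try in seq_len(max_tries)) {
    s1 <- rbinom(1L, 1L, n_plus / n) # 1 = CS+, 0 = CS-
    flips <- if (n > 1L) rbinom(n - 1L, 1L, p_alt) else integer(0)
    s <- (s1 + c(0L, cumsum(flips))) %% 2L
    if (sum(s) == n_plus) return(s)
  }
  stop("draw_type_sequence: could not draw a sequence with the requested ",
       "counts after ", max_tries, " tries")
}

# Place m CS- onsets uniformly, with spacing >= cs_duration, inside [lo, hi]
# (bounds are the admissible onset interval).
place_cs_minus <- function(m, lo, hi, cs_duration) {
  if (m == 0L) return(numeric(0))
  span <- hi - lo - (m - 1) * cs_duration
  if (span < 0) stop("place_cs_minus: interval too short for ", m, " trials")
  u <- sort(runif(m, 0, span))
  lo + u + (seq_len(m) - 1) * cs_duration
}

#' Generate the trial schedule of a synthetic 2CAP session
#'
#' Produces the session skeleton: `n_cs_plus` CS+ and `n_cs_minus` CS- trials.
#' CS+ onsets are separated by pseudorandomly drawn intertrial intervals from
#' `iti_set` (measured from the end of the preceding CS+ trial, cue plus
#' access, to the next onset). CS- trials fall strictly inside intertrial
#' intervals (or the lead-in/tail), at least `cs_minus_exclusion` seconds from
#' every flanking CS+ trial boundary. Consecutive trials differ in CS type
#' with probability `alternation_p` (default 0.6), reproducing the task's
#' elevated alternation likelihood.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to the config's seed.
#' @return a data.frame with columns `trial` (1-based, time order), `cs_type`
#'   (`"plus"`/`"minus"`), `cs_index` (1-based index within type),
#'   `side` (`"left"`/`"right"`, CS+ only), `cs_onset` (s).
#' @export
generate_schedule <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, {
    cs_dur <- config$cs_duration
    trial_len <- cs_dur + config$access_duration
    excl <- config$cs_minus_exclusion
    # the longest CS- run an intertrial interval can hold; type sequences
    # whose interior runs exceed it cannot be scheduled, so they are redrawn
    # (bounded rejection, like the count-conditioning in draw_type_sequence)
    max_run <- floor((max(config$iti_set) - 2 * excl) / cs_dur)
    for (try in seq_len(100L)) {
      types <- draw_type_sequence(config$n_cs_plus, config$n_cs_minus,
                                  config$alternation_p)
      plus_pos <- which(types == 1L)
      runs <- diff(c(0L, plus_pos)) - 1L    # CS- count before each CS+
      if (length(runs) < 2L || all(runs[-1] <= max_run)) break
    }
    tail_run <- length(types) - plus_pos[length(plus_pos)]

    onsets_plus <- numeric(config$n_cs_plus)
    onsets_minus <- numeric(0)
    # lead-in segment before the first CS+
    m0 <- runs[1]
    lead <- max(config$session_lead_in, 2 * excl + m0 * cs_dur + 1)
    t_prev_end <- 0
    first_onset <- t_prev_end + lead
    if (m0 > 0L) {
      onsets_minus <- c(onsets_minus,
                        place_cs_minus(m0, excl, first_onset - excl - cs_dur,
                                       cs_dur))
    }
    onsets_plus[1] <- first_onset
    if (config$n_cs_plus > 1L) {
      for (j in 2:config$n_cs_plus) {
        m <- runs[j]
        need <- 2 * excl + m * cs_dur
        ok <- config$iti_set[config$iti_set >= need]
        if (length(ok) == 0L) {
          stop("generate_schedule: no intertrial interval in {",
               paste(config$iti_set, collapse = ", "),
               "} can hold ", m, " CS- trial(s); need >= ", need, " s")
        }
        iti <- if (length(ok) == 1L) ok else sample(ok, 1L)
        prev_end <- onsets_plus[j - 1] + trial_len
        onsets_plus[j] <- prev_end + iti
        if (m > 0L) {
          onsets_minus <- c(onsets_minus,
                            place_cs_minus(m, prev_end + excl,
                                           onsets_plus[j] - excl - cs_dur,
                                           cs_dur))
        }
      }
    }
    if (tail_run > 0L) {
      last_end <- onsets_plus[config$n_cs_plus] + trial_len
      onsets_minus <- c(onsets_minus,
                        place_cs_minus(tail_run, last_end + excl,
                                       last_end + excl +
                                         (tail_run + 1) * cs_dur + 20,
                                       cs_dur))
    }
    sides <- sample(c("left", "right"), config$n_cs_plus, replace = TRUE)
    tab <- rbind(
      data.frame(cs_type = "plus", cs_index = seq_len(config$n_cs_plus),
                 side = sides, cs_onset = onsets_plus,
                 stringsAsFactors = FALSE),
      if (config$n_cs_minus > 0L) {
        data.frame(cs_type = "minus", cs_index = seq_len(config$n_cs_minus),
                   side = NA_character_, cs_onset = sort(onsets_minus),
                   stringsAsFactors = FALSE)
      }
    )
    tab <- tab[order(tab$cs_onset), , drop = FALSE]
    tab <- cbind(trial = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
    tab
  })
}

#' Check schedule legality
#'
#' Asserts, exhaustively over all trial pairs, that no CS- onset (or end)
#' falls within the exclusion period of any CS+ trial boundary and that CS-
#' trials do not overlap each other.
#'
#' @param schedule a schedule data.frame from [generate_schedule()].
#' @param config the generating [sim_config()].
#' @return TRUE invisibly; stops on the first violation found.
#' @export
assert_schedule_legal <- function(schedule, config) {
  cs_dur <- config$cs_duration
  trial_len <- cs_dur + config$access_duration
  excl <- config$cs_minus_exclusion
  plus <- schedule[schedule$cs_type == "plus", ]
  minus <- schedule[schedule$cs_type == "minus", ]
  for (i in seq_len(nrow(minus))) {
    m_on <- minus$cs_onset[i]
    m_end <- m_on + cs_dur
    # distance from CS- interval to every CS+ trial interval
    gap_before <- plus$cs_onset - m_end          # CS- entirely before CS+
    gap_after <- m_on - (plus$cs_onset + trial_len) # CS- entirely after
    ok <- (gap_before >= excl) | (gap_after >= excl)
    if (!all(ok)) {
      stop("CS- trial ", minus$trial[i], " violates the ", excl,
           " s exclusion around CS+ trial ", plus$trial[which(!ok)[1]])
    }
  }
  if (nrow(minus) > 1L) {
    if (any(diff(minus$cs_onset) < cs_dur)) stop("overlapping CS- trials")
  }
  invisible(TRUE)
}
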