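# Spike-train preprocessing: binning, adaptive Gaussian smoothing,
# peri-event alignment, z-scoring, trial-type averaging, concatenation.

#' Default peri-event windows, in 100-ms bins relative to the event
#'
#' `cs_plus` and `cs` span -10 s to +20 s around the CS onset, `approach_init`
#' -5 s to +2 s around approach initiation, `drink` -10 s to +10 s around the
#' drink time.
#' @return named list of inclusive `c(lo, hi)` relative-bin bounds.
#' @export
default_windows <- function() {
  list(cs_plus = c(-100L, 200L), cs = c(-100L, 200L),
       approach_init = c(-50L, 20L), drink = c(-100L, 100L))
}

#' Bin spike times into fixed-width count bins
#'
#' Bins are half-open `[k * bin_width, (k + 1) * bin_width)`. The default
#' 100-ms bins give the 10 Hz resolution used throughout the analysis.
#'
#' @param spikes data.frame with `unit_id` and `spike_time` (s, nonnegative,
#'   ascending within unit), or a named list of numeric spike-time vectors.
#' @param bin_width bin width in s (default 0.1).
#' @param duration session duration in s; must cover the last spike.
#' @return matrix units x bins of spike counts, with attributes `bin_width`
#'   and `t0` (= 0); rownames are unit ids.
#' @export
bin_spikes <- function(spikes, bin_width = 0.1, duration) {
  if (is.data.frame(spikes)) {
    spikes <- split(spikes$spike_time, spikes$unit_id)
  }
  n_bins <- as.integer(ceiling(duration / bin_width - 1e-9))
  breaks_check <- function(x) {
    if (length(x) == 0L) return(invisible(NULL))
    if (any(x < 0)) stop("bin_spikes: negative spike times")
    if (is.unsorted(x)) stop("bin_spikes: spike times must be ascending")
    if (max(x) >= duration + 1e-9) {
      stop("bin_spikes: duration (", duration, " s) is before the last spike")
    }
  }
  out <- matrix(0L, length(spikes), n_bins,
                dimnames = list(names(spikes), NULL))
  for (i in seq_along(spikes)) {
    breaks_check(spikes[[i]])
    if (length(spikes[[i]]) > 0L) {
      k <- pmin(floor(spikes[[i]] / bin_width), n_bins - 1L) + 1L
      tb <- tabulate(k, nbins = n_bins)
      out[i, ] <- tb
    }
  }
  attr(out, "bin_width") <- bin_width
  attr(out, "t0") <- 0
  out
}

#' Adaptive Gaussian smoothing of binned spike trains
#'
#' Convolves each unit's binned counts with a unit-mass discrete Gaussian
#' whose standard deviation is one-quarter of that unit's mean interspike
#' interval (a per-unit constant), truncated at +/- 4 SD. At the recording
#' boundaries the truncated kernel is renormalized on the source side so that
#' each spike's mass stays inside the recording: the total count is conserved
#' to machine precision. Units with fewer than two spikes (mean ISI
#' undefined) are passed through unsmoothed and flagged.
#'
#' @param counts units x bins count matrix from [bin_spikes()].
#' @param spikes the spike table (or list) the counts came from, used for the
#'   per-unit mean interspike interval.
#' @param sd_fraction kernel SD as a fraction of the mean ISI (default 0.25).
#' @return smoothed matrix with the same shape and attributes, plus attribute
#'   `unsmoothed_units` (character vector of flagged unit ids).
#' @export
smooth_adaptive <- function(counts, spikes, sd_fraction = 0.25) {
  if (is.data.frame(spikes)) spikes <- split(spikes$spike_time, spikes$unit_id)
  bw <- attr(counts, "bin_width")
  stopifnot(!is.null(bw))
  units <- rownames(counts)
  n <- ncol(counts)
  out <- counts * 0.0
  flagged <- character(0)
  for (i in seq_len(nrow(counts))) {
    uid <- units[i]
    st <- spikes[[uid]]
    if (is.null(st) || length(st) < 2L) {
      flagged <- c(flagged, uid %||% as.character(i))
      out[i, ] <- counts[i, ]
      next
    }
    sd_bins <- sd_fraction * mean(diff(st)) / bw
    out[i, ] <- gauss_smooth_conserve(as.numeric(counts[i, ]), sd_bins)
  }
  if (length(flagged) > 0L) {
    warning("smooth_adaptive: ", length(flagged),
            " unit(s) with < 2 spikes passed through unsmoothed")
  }
  attr(out, "bin_width") <- bw
  attr(out, "t0") <- attr(counts, "t0")
  attr(out, "unsmoothed_units") <- flagged
  out
}

# count-conserving truncated-Gaussian convolution of one vector
gauss_smooth_conserve <- function(x, sd_bins) {
  n <- length(x)
  h <- ceiling(4 * sd_bins)
  if (h < 1 || sd_bins < 1e-9) return(x)
  offs <- seq.int(-h, h)
  K <- dnorm(offs, sd = sd_bins)
  K <- K / sum(K)
  nz <- which(x != 0)
  if (length(nz) == 0L) return(x)
  IDX <- outer(nz, offs, "+")                      # m x W target bins
  WM <- outer(x[nz], K)                            # m x W mass
  valid <- IDX >= 1L & IDX <= n
  inmass <- rowSums(WM * valid)                    # mass landing inside
  WM <- WM * (x[nz] / inmass)                      # renormalize per source
  agg <- rowsum(WM[valid], IDX[valid])
  out <- numeric(n)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Extract event-aligned slices of a rate matrix
#'
#' One slice per event; relative bin 0 is the bin containing the event time.
#' Events whose window exceeds the recording are dropped (and reported in the
#' `dropped` attribute).
#'
#' @param rates units x bins matrix with a `bin_width` attribute.
#' @param events event times in s (absolute session time).
#' @param alignment one of `"cs_plus"`, `"cs"`, `"approach_init"`, `"drink"`;
#'   selects the default window.
#' @param window optional `c(lo, hi)` inclusive relative-bin override.
#' @return 3-d array units x events x relative bins with attributes `window`,
#'   `alignment`, `bin_width`, `kept` (indices into `events`) and `dropped`.
#' @export
extract_aligned <- function(rates, events,
                            alignment = c("cs_plus", "cs", "approach_init",
                                          "drink"),
                            window = NULL) {
  alignment <- match.arg(alignment)
  window <- window %||% default_windows()[[alignment]]
  bw <- attr(rates, "bin_width")
  stopifnot(!is.null(bw), length(window) == 2L, window[1] <= window[2])
  n_bins <- ncol(rates)
  k0 <- floor(events / bw + 1e-9)                  # 0-based event bin
  lo <- k0 + window[1]
  hi <- k0 + window[2]
  keep <- which(lo >= 0 & hi <= n_bins - 1L & !is.na(events))
  if (length(keep) == 0L) {
    stop("extract_aligned: no event survives the ", alignment, " window")
  }
  n_rel <- window[2] - window[1] + 1L
  out <- array(NA_real_, c(nrow(rates), length(keep), n_rel),
               dimnames = list(rownames(rates), NULL, NULL))
  for (e in seq_along(keep)) {
    cols <- (lo[keep[e]]:hi[keep[e]]) + 1L
    out[, e, ] <- rates[, cols]
  }
  structure(out, window = window, alignment = alignment, bin_width = bw,
            kept = keep, dropped = setdiff(seq_along(events), keep))
}

#' Z-score an aligned tensor per unit
#'
#' Each unit is standardized to mean 0, SD 1 over all its (trial, bin) cells
#' within the alignment. Units with (numerically) constant rate map to all
#' zeros and are flagged.
#'
#' @param tensor units x trials x bins array from [extract_aligned()].
#' @param sd_floor SDs below this are treated as zero (default 1e-12).
#' @return tensor of the same shape; attribute `constant_units` lists flagged
#'   unit ids.
#' @export
zscore_aligned <- function(tensor, sd_floor = 1e-12) {
  at <- attributes(tensor)
  flat <- matrix(tensor, nrow = dim(tensor)[1])
  mu <- rowMeans(flat)
  sdv <- apply(flat, 1, sd)
  const <- sdv < sd_floor
  sdv[const] <- 1
  z <- (flat - mu) / sdv
  z[const, ] <- 0
  out <- array(z, dim = dim(tensor), dimnames = dimnames(tensor))
  for (a in setdiff(names(at), c("dim", "dimnames"))) attr(out, a) <- at[[a]]
  attr(out, "constant_units") <- rownames(tensor)[const] %||% which(const)
  out
}

#' Average an aligned tensor over a two-cell trial partition
#'
#' @param tensor units x trials x bins array.
#' @param split logical vector over the tensor's trials: `TRUE` for the
#'   "positive" cell (e.g., pre-change-point, CS+, approach, drink).
#' @param cell_names names for the two cells (used in errors).
#' @return list with `plus` and `minus` (units x bins mean matrices) and
#'   trial counts `n_plus`, `n_minus`.
#' @export
average_trial_types <- function(tensor, split,
                                cell_names = c("positive", "negative")) {
  stopifnot(length(split) == dim(tensor)[2])
  if (!any(split)) stop("average_trial_types: empty cell '", cell_names[1], "'")
  if (all(split)) stop("average_trial_types: empty cell '", cell_names[2], "'")
  mean_over <- function(idx) {
    sub <- tensor[, idx, , drop = FALSE]
    apply(sub, c(1, 3), mean)
  }
  list(plus = mean_over(split), minus = mean_over(!split),
       n_plus = sum(split), n_minus = sum(!split))
}

segment_order <- c("a_plus", "a_minus", "b_plus", "b_minus",
                   "c_plus", "c_minus", "d_plus", "d_minus")

#' Concatenate the eight trial-type mean traces per neuron
#'
#' Builds each neuron's concatenated profile in the fixed segment order
#' `a+`, `a-` (pre/post change point, CS+ aligned), `b+`, `b-` (CS+/CS-),
#' `c+`, `c-` (approach/no approach), `d+`, `d-` (drink/no drink). With the
#' default windows the profile is 2 x (301 + 301 + 71 + 201) = 1748 bins.
#'
#' @param means named list of the 8 units x bins matrices, names as above.
#' @return units x total-bins matrix with attribute `segment_map`, a named
#'   list of 1-based column index ranges covering every bin exactly once.
#' @export
concatenate_profiles <- function(means) {
  missing_seg <- setdiff(segment_order, names(means))
  if (length(missing_seg) > 0L) {
    stop("concatenate_profiles: missing segment(s): ",
         paste(missing_seg, collapse = ", "))
  }
  units <- rownames(means[[segment_order[1]]])
  for (s in segment_order) {
    if (!identical(rownames(means[[s]]), units)) {
      stop("concatenate_profiles: inconsistent unit sets across segments")
    }
  }
  mats <- means[segment_order]
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seg_map <- mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
  names(seg_map) <- segment_order
  profile <- do.call(cbind, mats)
  rownames(profile) <- units
  colnames(profile) <- NULL
  attr(profile, "segment_map") <- seg_map
  profile
}

#' Column indices of a segment within a concatenated profile
#' @param profile matrix from [concatenate_profiles()] (or its segment map).
#' @param segment segment name, e.g. `"c_minus"`.
#' @return integer vector of 1-based column indices.
#' @export
segment_bins <- function(profile, segment) {
  sm <- if (is.list(profile)) profile else attr(profile, "segment_map")
  if (is.null(sm[[segment]])) stop("unknown segment: ", segment)
  sm[[segment]]
}
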