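# Putative excitatory/inhibitory classification from mean waveforms.

#' Normalize a mean waveform to the [-1, 1] depolarization scale
#'
#' Affine map sending the trough (maximum hyperpolarization) to -1 and the
#' post-trough maximum (post-action-potential depolarization peak) to +1.
#'
#' @param w numeric waveform samples (>= 16), trough not at the final sample.
#' @return normalized waveform (same length), with attributes `trough_index`
#'   and `peak_index`.
#' @export
normalize_waveform <- function(w) {
  w <- as.numeric(w)
  if (length(w) < 16L) stop("normalize_waveform: need >= 16 samples")
  i_tr <- which.min(w)
  if (i_tr >= length(w)) stop("normalize_waveform: trough at the final sample")
  post <- w[(i_tr + 1L):length(w)]
  i_pk <- i_tr + which.max(post)
  if (w[i_pk] == w[i_tr]) {
    stop("normalize_waveform: flat waveform (trough equals post-trough max)")
  }
  out <- -1 + 2 * (w - w[i_tr]) / (w[i_pk] - w[i_tr])
  structure(out, trough_index = i_tr, peak_index = i_pk)
}

#' Depolarization time delays of a normalized waveform
#'
#' Measured from the trough sample, `t50` is the first time the
#' post-trough rise crosses the 50% depolarization level (value 0 on the
#' [-1, 1] scale) and `t95` the 95% level (value 0.9), with linear
#' interpolation between samples.
#'
#' @param w normalized waveform from [normalize_waveform()].
#' @param sample_rate sampling rate in Hz (default 30000).
#' @return list with `t50` and `t95` in ms; errors (for outlier flagging) if
#'   the rise never reaches the 95% level.
#' @export
depolarization_delays <- function(w, sample_rate = 30000) {
  i_tr <- attr(w, "trough_index")
  if (is.null(i_tr)) {
    w <- normalize_waveform(w)
    i_tr <- attr(w, "trough_index")
  }
  rise <- w[i_tr:length(w)]
  cross_time <- function(level) {
    above <- which(rise >= level)[1]
    if (is.na(above)) {
      stop("depolarization_delays: rise never reaches level ", level,
           "; unit flagged outlier")
    }
    if (above == 1L) return(0)
    frac <- (level - rise[above - 1L]) / (rise[above] - rise[above - 1L])
    (above - 2L + frac)
  }
  dt_ms <- 1000 / sample_rate
  t50 <- cross_time(0) * dt_ms
  t95 <- cross_time(0.9) * dt_ms
  list(t50 = t50, t95 = t95)
}

#' Waveform features for a set of units
#'
#' @param waveforms units x samples matrix (rownames = unit ids).
#' @param sample_rate sampling rate in Hz (default: the matrix's
#'   `sample_rate` attribute, else 30000).
#' @return data.frame `unit_id`, `t50`, `t95` (ms), logical `feature_ok`
#'   (FALSE when the rise never reaches the 95% level: outlier).
#' @export
waveform_features <- function(waveforms, sample_rate = NULL) {
  sample_rate <- sample_rate %||% attr(waveforms, "sample_rate") %||% 30000
  ids <- rownames(waveforms) %||% as.character(seq_len(nrow(waveforms)))
  out <- data.frame(unit_id = ids, t50 = NA_real_, t95 = NA_real_,
                    feature_ok = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(waveforms))) {
    res <- tryCatch({
      d <- depolarization_delays(normalize_waveform(waveforms[i, ]),
                                 sample_rate)
      out$t50[i] <- d$t50
      out$t95[i] <- d$t95
      out$feature_ok[i] <- TRUE
      NULL
    }, error = function(e) e)
  }
  out
}

#' Classify units as putative excitatory/inhibitory/outlier
#'
#' A seeded 2-means partition of the standardized (t50, t95) features stands
#' in for the manual clustering step: the cluster with the smaller mean t95
#' (fast depolarization) is putative inhibitory, the other putative
#' excitatory. Points farther than `outlier_sd` standardized units from their
#' cluster centroid on either feature, and units whose rise never reached the
#' 95% level, are labeled outliers. Features are computed after amplitude
#' normalization, so the labels are invariant to waveform scaling.
#'
#' @param features data.frame from [waveform_features()].
#' @param seed integer seed for the 2-means initialization.
#' @param outlier_sd outlier distance threshold in per-feature SD units
#'   (default 4).
#' @return the features data.frame with a `class` column in
#'   `c("putative_excitatory", "putative_inhibitory", "outlier")`.
#' @export
classify_units <- function(features, seed = 1L, outlier_sd = 4) {
  ok <- which(features$feature_ok)
  if (length(ok) < 10L) {
    stop("classify_units: need >= 10 units with valid features, got ",
         length(ok))
  }
  stopifnot(all(features$t50[ok] <= features$t95[ok]))
  Z <- scale(cbind(features$t50[ok], features$t95[ok]))
  Z[is.nan(Z)] <- 0
  km <- with_seed(seed, kmeans(Z, centers = 2L, nstart = 10L))
  mean_t95 <- tapply(features$t95[ok], km$cluster, mean)
  inhib_cluster <- as.integer(names(mean_t95)[which.min(mean_t95)])
  lab <- ifelse(km$cluster == inhib_cluster,
                "putative_inhibitory", "putative_excitatory")
  dev <- abs(Z - km$centers[km$cluster, , drop = FALSE])
  lab[apply(dev, 1, max) > outlier_sd] <- "outlier"
  features$class <- "outlier"
  features$class[ok] <- lab
  features
}

#' Per-class firing-rate change in an analysis epoch
#'
#' For every unit, the mean rate over the epoch bins on event trials minus
#' the mean on non-event trials, aggregated per waveform class (and
#' optionally per group).
#'
#' @param tensor units x trials x bins rate array (Hz, event-aligned, not
#'   z-scored).
#' @param labels named character vector of unit classes (names = unit ids in
#'   tensor row order, or a vector in row order).
#' @param epoch_bins indices into the tensor's relative bins.
#' @param split logical per-trial vector: TRUE = event trials.
#' @param groups optional per-unit group labels.
#' @return list with `per_unit` (data.frame of per-unit changes) and
#'   `summary` (mean, sem, n per class x group); classes with zero units are
#'   omitted.
#' @export
epoch_rate_change_by_class <- function(tensor, labels, epoch_bins, split,
                                       groups = NULL) {
  stopifnot(length(split) == dim(tensor)[2])
  if (!any(split) || all(split)) {
    stop("epoch_rate_change_by_class: both trial cells must be non-empty")
  }
  n_units <- dim(tensor)[1]
  ids <- rownames(tensor) %||% as.character(seq_len(n_units))
  if (!is.null(names(labels))) labels <- labels[ids]
  groups <- groups %||% rep("all", n_units)
  ev <- apply(tensor[, split, epoch_bins, drop = FALSE], 1, mean)
  nev <- apply(tensor[, !split, epoch_bins, drop = FALSE], 1, mean)
  per_unit <- data.frame(unit_id = ids, class = unname(labels),
                         group = groups, change = ev - nev,
                         stringsAsFactors = FALSE)
  agg <- aggregate(change ~ class + group, data = per_unit, FUN = function(v) {
    c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v))
  })
  summary <- data.frame(class = agg$class, group = agg$group,
                        mean = agg$change[, "mean"], sem = agg$change[, "sem"],
                        n = agg$change[, "n"])
  list(per_unit = per_unit, summary = summary)
}
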