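# End-to-end pipeline: behavior -> preprocessing -> subsampled PCA ->
# separations -> waveform classes, over one or more session bundles.

#' Pipeline configuration
#'
#' Collects every analysis default in one place. Unknown keys are rejected.
#' All randomness downstream flows from the single root `seed`.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `pipeline_config` with a `hash` attribute.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    bin_width = 0.1,          # s; 10 Hz analysis resolution
    sd_fraction = 0.25,       # smoothing SD as fraction of mean ISI
    windows = default_windows(),
    q_window = c(0, 12),      # s after CS onset for approach likelihood
    drink_radius = 9,         # px
    n_iterations = 500L,
    n_per_group = 200L,
    n_pcs = 10L,
    epochs = default_epochs(),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Behavioral and spike preprocessing of one session
#'
#' Runs the session-level stages: session change point from the binary CS+
#' approach sequence; approach-likelihood change points for per-trial
#' approach initiation; surrogate initiation/drink times for no-event trials;
#' drink detection from tracking; spike binning, adaptive smoothing, the four
#' event alignments, and per-alignment z-scoring.
#'
#' @param bundle a loaded session bundle (or [simulate_session()] output).
#' @param config a [pipeline_config()].
#' @return list of class `session_data` with `tensors` (z-scored a/b/c/d),
#'   `tensors_hz` (d alignment in Hz, for rate summaries), `splits`,
#'   `j_scp`, `trials` (augmented), `behavior` (metrics), `units`,
#'   `waveforms`, `group`, `animal`, `session_id`.
#' @export
process_session <- function(bundle, config = pipeline_config()) {
  tr <- bundle$trials
  seed0 <- derive_seed(config$seed, label_key(bundle$session_id %||% "s"))
  plus_idx <- which(tr$cs_type == "plus")
  plus <- tr[plus_idx, ]
  plus <- plus[order(plus$cs_index), ]
  scp <- session_change_point(as.numeric(plus$approach))
  if (is.na(scp$j_scp)) {
    stop("process_session: constant approach sequence in session ",
         bundle$session_id, "; no seeking change point")
  }

  q <- approach_likelihood(plus, bundle$tracking, window = config$q_window,
                           bin_width = config$bin_width)
  ai <- detect_approach_initiation(q)
  plus$approach_init <- NA_real_
  plus$approach_init[ai$trial] <- ai$approach_init
  plus$approach_init[!plus$approach] <- NA_real_
  plus <- assign_surrogate_times(plus, "approach",
                                 seed = derive_seed(seed0, 11L))

  plus$drink_time <- detect_drink_initiation(plus, bundle$tracking,
                                             bundle$sippers,
                                             bundle$manifest$config %||%
                                               bundle$config,
                                             radius = config$drink_radius)
  drink_split_real <- plus$correct & !is.na(plus$drink_time)
  plus$drink_time[!drink_split_real] <- NA_real_
  plus <- assign_surrogate_times(plus, "drink",
                                 seed = derive_seed(seed0, 12L))

  duration <- max(bundle$tracking$time) + 1
  counts <- bin_spikes(bundle$spikes, config$bin_width, duration)
  silent <- setdiff(bundle$units$unit_id, rownames(counts))
  if (length(silent) > 0L) { # units with no spikes still get (zero) rows
    counts <- rbind(counts,
                    matrix(0L, length(silent), ncol(counts),
                           dimnames = list(silent, NULL)))
  }
  counts <- counts[bundle$units$unit_id, , drop = FALSE]
  attr(counts, "bin_width") <- config$bin_width
  rates <- smooth_adaptive(counts, bundle$spikes,
                           sd_fraction = config$sd_fraction)

  mk <- function(events, alignment) {
    extract_aligned(rates, events, alignment, config$windows[[alignment]])
  }
  a <- mk(plus$cs_onset, "cs_plus")
  b <- mk(tr$cs_onset, "cs")
  c_t <- mk(plus$cs_onset + plus$approach_init, "approach_init")
  d <- mk(plus$cs_onset + plus$drink_time, "drink")

  splits <- list(
    a = (plus$cs_index < scp$j_scp)[attr(a, "kept")],
    b = (tr$cs_type == "plus")[attr(b, "kept")],
    c = plus$approach[attr(c_t, "kept")],
    d = drink_split_real[attr(d, "kept")]
  )
  tensors <- list(a = zscore_aligned(a), b = zscore_aligned(b),
                  c = zscore_aligned(c_t), d = zscore_aligned(d))
  d_hz <- d / config$bin_width
  for (at in c("window", "alignment", "bin_width", "kept", "dropped")) {
    attr(d_hz, at) <- attr(d, at)
  }

  metrics <- session_metrics(tr, bundle$tracking, bundle$sippers,
                             bundle$manifest$config %||% bundle$config,
                             radius = config$drink_radius)
  structure(list(
    tensors = tensors, tensors_hz = list(d = d_hz), splits = splits,
    j_scp = scp$j_scp, scp_magnitude = scp$magnitude, trials = plus,
    behavior = list(cs_sensitivity = cs_sensitivity(tr), metrics = metrics),
    units = bundle$units, waveforms = bundle$waveforms,
    group = bundle$group, animal = bundle$animal,
    session_id = bundle$session_id
  ), class = "session_data")
}

#' Pool concatenated profiles across sessions
#'
#' Averages each session's z-scored tensors over its own trial partitions,
#' concatenates the eight segments per neuron, and stacks neurons across
#' sessions.
#'
#' @param sessions list of [process_session()] results.
#' @return list with `profiles` (units x bins), `groups`, `animals`,
#'   `unit_ids`, `seg_map`.
#' @export
build_profiles <- function(sessions) {
  prof <- list(); groups <- c(); animals <- c(); ids <- c()
  seg_map <- NULL
  for (s in sessions) {
    means <- list()
    for (al in c("a", "b", "c", "d")) {
      avg <- average_trial_types(s$tensors[[al]], s$splits[[al]])
      means[[paste0(al, "_plus")]] <- avg$plus
      means[[paste0(al, "_minus")]] <- avg$minus
    }
    p <- concatenate_profiles(means)
    seg_map <- attr(p, "segment_map")
    prof[[length(prof) + 1L]] <- p
    groups <- c(groups, s$units$group)
    animals <- c(animals, s$units$animal %||% rep(s$animal, nrow(p)))
    ids <- c(ids, rownames(p))
  }
  profiles <- do.call(rbind, prof)
  attr(profiles, "segment_map") <- seg_map
  list(profiles = profiles, groups = groups, animals = animals,
       unit_ids = ids, seg_map = seg_map)
}

#' Subsampled-PCA separation analysis over sessions
#'
#' The core population analysis: pooled concatenated profiles, group-matched
#' subsampled PCA with sign alignment and stability selection, per-group
#' trajectories over the stable components, and per-epoch separation
#' summaries.
#'
#' @param sessions list of [process_session()] results (or a pre-built
#'   [build_profiles()] result via `profiles_in`).
#' @param config a [pipeline_config()].
#' @param profiles_in optional pre-built profiles (overrides `sessions`).
#' @return list with `profiles`, `result`, `stability`, `stable_pcs`,
#'   `trajectories` (per group), `separations` (group -> epoch ->
#'   list(values, mean, n_bins)).
#' @export
population_analysis <- function(sessions, config = pipeline_config(),
                                profiles_in = NULL) {
  bp <- profiles_in %||% build_profiles(sessions)
  design <- subsample_design(bp$groups, config$n_iterations,
                             config$n_per_group,
                             seed = derive_seed(config$seed, 101L))
  res <- run_subsampled_pca(bp$profiles, design, config$n_pcs)
  res <- align_pc_signs(res)
  stab <- pc_stability(res)
  stable <- stab$pc[stab$stable]
  trajectories <- list()
  separations <- list()
  for (g in unique(bp$groups)) {
    traj <- project_group(bp$profiles, res, g,
                          pcs = if (length(stable) > 0) stable else 1L)
    trajectories[[g]] <- traj
    separations[[g]] <- lapply(config$epochs, function(ep) {
      epoch_mean_separation(traj, bp$seg_map, ep, config$windows)
    })
  }
  list(profiles = bp, result = res, stability = stab, stable_pcs = stable,
       trajectories = trajectories, separations = separations)
}

#' Shuffle null for an epoch's separation
#'
#' Permutes the trial-type assignment of one alignment within each session,
#' recomputes the full downstream analysis (means, profiles, subsampled PCA,
#' stability, projections), and collects the null distribution of the epoch's
#' mean separation per group. The subsample design seed is held fixed so the
#' identity permutation reproduces the observed value exactly.
#'
#' @param sessions list of [process_session()] results.
#' @param config a [pipeline_config()].
#' @param alignment which trial split to shuffle (`"a"`, `"b"`, `"c"`, `"d"`).
#' @param epoch epoch name (must exist in `config$epochs`).
#' @param n_shuffles number of label permutations (default 100).
#' @param seed integer seed for the permutations.
#' @return list with `observed` (named per-group epoch means) and `null`
#'   (n_shuffles x groups matrix).
#' @export
shuffle_null <- function(sessions, config = pipeline_config(),
                         alignment = "a", epoch = "seeking",
                         n_shuffles = 100L, seed = 1L) {
  stopifnot(epoch %in% names(config$epochs))
  run_once <- function(ss) {
    pa <- population_analysis(ss, config)
    vapply(pa$separations, function(se) se[[epoch]]$mean, numeric(1))
  }
  observed <- run_once(sessions)
  null <- matrix(NA_real_, n_shuffles, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (s in seq_len(n_shuffles)) {
    perm_sessions <- lapply(seq_along(sessions), function(i) {
      ses <- sessions[[i]]
      ses$splits[[alignment]] <- with_seed(
        derive_seed(seed, s * 1000L + i),
        sample(ses$splits[[alignment]])
      )
      ses
    })
    null[s, ] <- run_once(perm_sessions)
  }
  list(observed = observed, null = null)
}

#' Leave-one-animal-out sensitivity analysis
#'
#' Reruns the full population analysis once per held-out animal and tabulates
#' the per-epoch separation summaries. Holdouts that leave any group with
#' fewer units than the subsample size are skipped with a warning.
#'
#' @param sessions list of [process_session()] results.
#' @param config a [pipeline_config()].
#' @return data.frame `holdout`, `group`, `epoch`, `mean_separation`.
#' @export
leave_one_out <- function(sessions, config = pipeline_config()) {
  animals <- unique(vapply(sessions, function(s) s$animal, character(1)))
  out <- list()
  for (a in animals) {
    keep <- Filter(function(s) s$animal != a, sessions)
    if (length(keep) == 0L) next
    bp <- build_profiles(keep)
    if (any(table(bp$groups) < config$n_per_group)) {
      warning("leave_one_out: holdout of ", a,
              " empties a group below n_per_group; skipped")
      next
    }
    pa <- population_analysis(NULL, config, profiles_in = bp)
    for (g in names(pa$separations)) {
      for (ep in names(pa$separations[[g]])) {
        out[[length(out) + 1L]] <- data.frame(
          holdout = a, group = g, epoch = ep,
          mean_separation = pa$separations[[g]][[ep]]$mean)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full pipeline over session bundles and write results
#'
#' Executes behavior, preprocessing, population PCA, and waveform
#' classification in order and writes plain-text result tables plus a JSON
#' metadata record (including the configuration hash) to `out_dir`.
#' Re-running with identical inputs and configuration reproduces the outputs.
#'
#' @param bundles list of loaded session bundles (or [simulate_session()]
#'   outputs).
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the in-memory results list.
#' @export
run_pipeline <- function(bundles, config = pipeline_config(), out_dir) {
  sessions <- lapply(bundles, function(b) {
    tryCatch(process_session(b, config),
             error = function(e) stop("stage 'behavior/preprocess' failed ",
                                      "for session ", b$session_id, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  pa <- population_analysis(sessions, config)

  wf <- do.call(rbind, lapply(bundles, function(b) b$waveforms))
  sr <- attr(bundles[[1]]$waveforms, "sample_rate") %||% 30000
  feats <- waveform_features(wf, sr)
  labels <- classify_units(feats, seed = derive_seed(config$seed, 201L))

  drink_changes <- list()
  for (s in sessions) {
    lab_s <- setNames(labels$class, labels$unit_id)[rownames(s$tensors_hz$d)]
    ok <- any(s$splits$d) && !all(s$splits$d)
    if (ok) {
      drink_changes[[length(drink_changes) + 1L]] <-
        epoch_rate_change_by_class(
          s$tensors_hz$d, lab_s,
          epoch_bins = config$epochs$drink$rel_bins -
            config$windows$drink[1] + 1L,
          split = s$splits$d,
          groups = rep(s$group, nrow(s$tensors_hz$d)))$per_unit
    }
  }
  drink_change <- do.call(rbind, drink_changes)

  behavior_summary <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(session_id = s$session_id, group = s$group, animal = s$animal,
               j_scp = s$j_scp, scp_magnitude = s$scp_magnitude,
               cs_sensitivity = s$behavior$cs_sensitivity,
               prop_approached = s$behavior$metrics$prop_approached,
               median_latency =
                 median(s$behavior$metrics$latency, na.rm = TRUE),
               mean_time_at_sipper =
                 mean(s$behavior$metrics$time_at_sipper, na.rm = TRUE))
  }))

  sep_rows <- list()
  for (g in names(pa$separations)) {
    for (ep in names(pa$separations[[g]])) {
      se <- pa$separations[[g]][[ep]]
      sep_rows[[length(sep_rows) + 1L]] <- data.frame(
        group = g, epoch = ep, bin = seq_len(se$n_bins),
        separation = se$values)
    }
  }
  separation <- do.call(rbind, sep_rows)
  epoch_summary <- aggregate(separation ~ group + epoch, separation, mean)
  names(epoch_summary)[3] <- "mean_separation"

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                         row.names = FALSE)
  wr(pa$stability, "stability.csv")
  wr(separation, "separation.csv")
  wr(epoch_summary, "epoch_summary.csv")
  wr(behavior_summary, "behavior_summary.csv")
  wr(labels, "unit_labels.csv")
  if (!is.null(drink_change)) wr(drink_change, "drink_rate_change.csv")
  traj_rows <- do.call(rbind, lapply(names(pa$trajectories), function(g) {
    tj <- pa$trajectories[[g]]
    data.frame(group = g, bin = seq_len(nrow(tj)), as.data.frame(tj))
  }))
  wr(traj_rows, "trajectories.csv")
  meta <- list(config = unclass(config), config_hash = attr(config, "hash"),
               n_sessions = length(sessions),
               n_units = nrow(pa$profiles$profiles),
               stable_pcs = pa$stable_pcs,
               epochs = lapply(config$epochs, function(e) {
                 e$rel_bins <- range(e$rel_bins); e
               }))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sessions = sessions, population = pa, labels = labels,
                 behavior_summary = behavior_summary,
                 epoch_summary = epoch_summary,
                 drink_change = drink_change))
}

#' Summarize a results directory
#'
#' Reads the tables written by [run_pipeline()] and produces summary tables
#' (stability, epoch separations per group, behavior) plus separation
#' time-series plots when ggplot2 is available. Missing optional sections
#' (e.g., waveform labels) are marked absent rather than failing.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @param plot write `separation.pdf` (requires ggplot2).
#' @return list of summary data.frames.
#' @export
write_report <- function(results_dir, plot = TRUE) {
  need <- c("stability.csv", "separation.csv", "epoch_summary.csv",
            "behavior_summary.csv")
  missing_f <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing_f) > 0L) {
    stop("write_report: incomplete results, missing: ",
         paste(missing_f, collapse = ", "))
  }
  rd <- function(f) utils::read.csv(file.path(results_dir, f))
  rep <- list(stability = rd("stability.csv"),
              epoch_summary = rd("epoch_summary.csv"),
              behavior = rd("behavior_summary.csv"))
  lab_f <- file.path(results_dir, "unit_labels.csv")
  rep$unit_classes <- if (file.exists(lab_f)) {
    tab <- utils::read.csv(lab_f)
    as.data.frame(table(class = tab$class))
  } else {
    data.frame(class = "absent", Freq = NA)
  }
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    sep <- rd("separation.csv")
    p <- ggplot2::ggplot(sep, ggplot2::aes(x = bin, y = separation,
                                           color = group)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~epoch, scales = "free") +
      ggplot2::labs(x = "epoch bin (100 ms)", y = "PC separation")
    ggplot2::ggsave(file.path(results_dir, "separation.pdf"), p,
                    width = 8, height = 5)
  }
  utils::write.csv(rep$unit_classes,
                   file.path(results_dir, "report_unit_classes.csv"),
                   row.names = FALSE)
  rep
}
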