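# Session-bundle I/O: plain-text (CSV/JSON) round trip with validation.

#' Write a synthetic session to a bundle directory
#'
#' A session bundle is a directory of columnar CSV tables (comma, UTF-8,
#' header row) plus a JSON manifest recording the session id, group/animal
#' labels, file names, conventions (bin width, time origin, coordinate
#' units), and the generating configuration with its hash. Ground truth is
#' written alongside the data in a separate table; the analysis path never
#' reads it.
#'
#' @param dir target directory (created if needed).
#' @param session_id character id.
#' @param group experimental group label.
#' @param animal animal id.
#' @param trials,tracking,spikes,units,waveforms,truth session components
#'   (see [generate_schedule()], [simulate_tracking()],
#'   [simulate_population()]).
#' @param sippers named list of sipper coordinates.
#' @param config the generating [sim_config()].
#' @return the manifest, invisibly.
#' @export
write_session_bundle <- function(dir, session_id, group, animal,
                                 trials, tracking, spikes, units, waveforms,
                                 truth, sippers, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(trials = "trials.csv", tracking = "tracking.csv",
             spikes = "spikes.csv", units = "units.csv",
             waveforms = "waveforms.csv", truth = "ground_truth.csv")
  utils::write.csv(trials, file.path(dir, files["trials"]), row.names = FALSE)
  utils::write.csv(tracking, file.path(dir, files["tracking"]),
                   row.names = FALSE)
  utils::write.csv(spikes, file.path(dir, files["spikes"]), row.names = FALSE)
  utils::write.csv(units, file.path(dir, files["units"]), row.names = FALSE)
  wf <- as.data.frame(waveforms)
  names(wf) <- paste0("s", seq_len(ncol(wf)))
  wf <- cbind(unit_id = rownames(waveforms), wf)
  utils::write.csv(wf, file.path(dir, files["waveforms"]), row.names = FALSE)
  tt <- truth$trials_truth %||% truth
  if (is.data.frame(tt)) {
    utils::write.csv(tt, file.path(dir, files["truth"]), row.names = FALSE)
  }
  cfg <- config
  class(cfg) <- NULL
  manifest <- list(
    session_id = session_id, group = group, animal = animal,
    files = as.list(files),
    conventions = list(bin_width = 0.1, time_origin = "session start",
                       time_unit = "s", coordinate_unit = "px",
                       waveform_sample_rate =
                         attr(waveforms, "sample_rate") %||% 30000),
    sippers = sippers,
    config = cfg,
    config_hash = config_hash(cfg)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load and validate a session bundle
#'
#' Parses every table referenced by the manifest, schema-checks the required
#' columns, and cross-references unit ids across the spike, unit, and
#' waveform tables. All violations are collected and reported in a single
#' error.
#'
#' @param dir bundle directory containing `manifest.json`.
#' @return list of class `session_bundle` with the parsed tables, sipper
#'   coordinates, manifest, and a `parse_report` (character vector, empty
#'   when clean).
#' @export
load_session_bundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("load_session_bundle: no manifest in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  violations <- character(0)
  tabs <- list()
  for (nm in names(manifest$files)) {
    p <- file.path(dir, manifest$files[[nm]])
    if (!file.exists(p)) {
      violations <- c(violations, paste0("missing file: ", manifest$files[[nm]]))
      next
    }
    tabs[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  need <- list(trials = c("trial", "cs_type", "cs_index", "side", "cs_onset"),
               tracking = c("time", "x", "y"),
               spikes = c("unit_id", "spike_time"),
               units = c("unit_id", "group"))
  for (nm in names(need)) {
    if (is.null(tabs[[nm]])) next
    miss <- setdiff(need[[nm]], names(tabs[[nm]]))
    if (length(miss) > 0L) {
      violations <- c(violations, paste0(nm, ": missing column(s) ",
                                         paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(tabs$units) && anyDuplicated(tabs$units$unit_id)) {
    violations <- c(violations, paste0(
      "units: duplicated unit id ",
      tabs$units$unit_id[duplicated(tabs$units$unit_id)][1]))
  }
  if (!is.null(tabs$spikes) && all(c("unit_id", "spike_time") %in%
                                   names(tabs$spikes))) {
    bad <- vapply(split(tabs$spikes$spike_time, tabs$spikes$unit_id),
                  is.unsorted, logical(1))
    if (any(bad)) {
      violations <- c(violations, paste0("spikes: unsorted spike times for ",
                                         "unit ", names(bad)[bad][1]))
    }
    if (any(tabs$spikes$spike_time < 0)) {
      violations <- c(violations, "spikes: negative spike times")
    }
    if (!is.null(tabs$units)) {
      orphan <- setdiff(unique(tabs$spikes$unit_id), tabs$units$unit_id)
      if (length(orphan) > 0L) {
        violations <- c(violations, paste0("spikes: unit id(s) absent from ",
                                           "units table: ",
                                           paste(utils::head(orphan, 3),
                                                 collapse = ", ")))
      }
    }
  }
  if (length(violations) > 0L) {
    stop("load_session_bundle: ", length(violations), " violation(s):\n  ",
         paste(violations, collapse = "\n  "))
  }
  wf <- NULL
  if (!is.null(tabs$waveforms)) {
    wf <- as.matrix(tabs$waveforms[, -1, drop = FALSE])
    rownames(wf) <- tabs$waveforms$unit_id
    attr(wf, "sample_rate") <-
      manifest$conventions$waveform_sample_rate %||% 30000
  }
  sippers <- lapply(manifest$sippers, as.numeric)
  structure(list(session_id = manifest$session_id, group = manifest$group,
                 animal = manifest$animal, trials = tabs$trials,
                 tracking = tabs$tracking, spikes = tabs$spikes,
                 units = tabs$units, waveforms = wf, sippers = sippers,
                 manifest = manifest, parse_report = character(0)),
            class = "session_bundle")
}

#' Generate a complete synthetic session and write it as a bundle
#'
#' Convenience wrapper chaining [generate_schedule()], [simulate_behavior()],
#' [simulate_tracking()], and [simulate_population()] for a single group
#' label, optionally writing the result to disk.
#'
#' @param config a [sim_config()] (its `signal_gains` must contain `group`).
#' @param group group label for this session's units.
#' @param animal animal id (default = session id).
#' @param session_id session id string.
#' @param seed root seed for the session.
#' @param dir optional output directory; if `NULL` the session is returned in
#'   memory only.
#' @return list with `trials`, `tracking`, `sippers`, `spikes`, `units`,
#'   `waveforms`, `truth` (trial and unit ground truth), `config`.
#' @export
simulate_session <- function(config, group = names(config$signal_gains)[1],
                             animal = session_id, session_id = "s01",
                             seed = config$seed, dir = NULL) {
  sched <- generate_schedule(config, seed = derive_seed(seed, 1L))
  beh <- simulate_behavior(sched, config, seed = derive_seed(seed, 2L))
  trk <- simulate_tracking(beh$trials, config, seed = derive_seed(seed, 3L))
  if (!group %in% names(config$signal_gains)) {
    stop("simulate_session: group '", group, "' has no entry in ",
         "config$signal_gains (available: ",
         paste(names(config$signal_gains), collapse = ", "), ")")
  }
  cfg_g <- config
  cfg_g$signal_gains <- config$signal_gains[group]
  pop <- simulate_population(beh$trials, trk$truth, cfg_g,
                             seed = derive_seed(seed, 4L))
  pop$units$animal <- animal
  pop$units$session_id <- session_id
  out <- list(session_id = session_id, group = group, animal = animal,
              trials = beh$trials, tracking = trk$tracking,
              sippers = trk$sippers, spikes = pop$spikes, units = pop$units,
              waveforms = pop$waveforms,
              truth = list(trials_truth = cbind(trk$truth,
                                                approach = beh$trials$approach,
                                                drink = beh$trials$drink),
                           change_point_trial =
                             beh$truth$change_point_trial,
                           unit_class = pop$truth$class,
                           loadings = pop$truth$loadings),
              config = cfg_g)
  if (!is.null(dir)) {
    write_session_bundle(dir, session_id, group, animal, beh$trials,
                         trk$tracking, pop$spikes, pop$units, pop$waveforms,
                         out$truth, trk$sippers, cfg_g)
  }
  out
}
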