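#!/usr/bin/env Rscript

# Simulate a cohort of 2CAP sessions with planted ground truth and write each
# one as a text session bundle under data/sessions/.
#
# Two groups of animals are simulated: "compulsive" sessions carry a stronger
# planted seeking signal (pre-CS offset on pre-change-point CS+ trials) than
# "non_compulsive" sessions; all other signal gains match.

suppressPackageStartupMessages(library(twocap))

root_seed <- 20240601L
data_dir <- file.path("data", "sessions")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- expand.grid(group = c("compulsive", "non_compulsive"),
                      animal_idx = 1:3, stringsAsFactors = FALSE)
gains <- list(
  compulsive = c(seek = 1.5, cue = 1, approach = 1, drink = 1),
  non_compulsive = c(seek = 0.5, cue = 1, approach = 1, drink = 1)
)

manifest_rows <- list()
for (i in seq_len(nrow(cohort))) {
  g <- cohort$group[i]
  animal <- sprintf("%s_rat%02d", g, cohort$animal_idx[i])
  session_id <- sprintf("s%02d", i)
  seed <- derive_seed(root_seed, i)
  cfg <- sim_config(n_neurons = 60L, baseline_rate = 3,
                    loading_spread = 0.1,
                    signal_gains = setNames(list(gains[[g]]), g),
                    seed = seed)
  dir <- file.path(data_dir, session_id)
  s <- simulate_session(cfg, group = g, animal = animal,
                        session_id = session_id, seed = seed, dir = dir)
  manifest_rows[[i]] <- data.frame(
    session_id = session_id, group = g, animal = animal, seed = seed,
    n_units = nrow(s$units), n_trials = nrow(s$trials),
    true_change_point = s$truth$change_point_trial,
    seek_gain = gains[[g]]["seek"])
  cat("wrote", dir, "(", nrow(s$units), "units )\n")
}

dir.create("results", showWarnings = FALSE)
utils::write.csv(do.call(rbind, manifest_rows),
                 file.path("results", "cohort_manifest.csv"),
                 row.names = FALSE)
cat("cohort manifest -> results/cohort_manifest.csv\n")
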