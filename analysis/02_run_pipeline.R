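#!/usr/bin/env Rscript

# Load the session bundles written by 01_simulate_sessions.R and run the full
# population analysis: behavioral change points and event detection, spike
# preprocessing, concatenated profiles, subsampled PCA with stability
# selection, group trajectory projections, epoch separations, and waveform
# classification. Tables land in results/.

suppressPackageStartupMessages(library(twocap))

data_dir <- file.path("data", "sessions")
dirs <- list.dirs(data_dir, recursive = FALSE)
if (length(dirs) == 0L) stop("no session bundles; run 01_simulate_sessions.R")

bundles <- lapply(dirs, load_session_bundle)
cat("loaded", length(bundles), "session bundles\n")

# analysis scale: 100 subsample iterations of 120 units per group (each group
# has 3 sessions x 60 units = 180 units)
pcfg <- pipeline_config(n_iterations = 100L, n_per_group = 120L,
                        n_pcs = 10L, seed = 20240602L)

res <- run_pipeline(bundles, pcfg, out_dir = "results")
cat("stable PCs:", paste(res$population$stable_pcs, collapse = ", "), "\n")
print(res$epoch_summary)
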