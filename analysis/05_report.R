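#!/usr/bin/env Rscript

# Summarize the results/ tables into a compact report: unit-class counts, a
# separation figure (if ggplot2 is available), and a console digest.

suppressPackageStartupMessages(library(twocap))

if (!file.exists(file.path("results", "stability.csv"))) {
  stop("no results tables; run 02_run_pipeline.R first")
}

rep <- write_report("results", plot = requireNamespace("ggplot2",
                                                       quietly = TRUE))

cat("\n-- stability --\n")
print(rep$stability)
cat("\n-- epoch separations --\n")
print(rep$epoch_summary)
cat("\n-- unit classes --\n")
print(rep$unit_classes)
cat("\n-- behavior --\n")
print(rep$behavior)
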