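#!/usr/bin/env Rscript
# Extract the 46-feature panel from every study in the simulated cohort and
# compute per-reader repeatability tables (one per feature class, mirroring
# a seven-table layout: histogram, fractal, GLCM, GLDM, NGTDM, run-length,
# zone-size).

library(texrep)

manifest <- "scratch/cohort/manifest.csv"
if (!file.exists(manifest)) stop("run analysis/01_simulate.R first")

res <- run_study(manifest, config = run_config(), out_dir = "results/run")

n_study <- length(unique(paste(res$features$subject_id, res$features$day,
                               res$features$reader_id)))
cat("extracted", nrow(res$features), "feature values from", n_study,
    "studies\n")
for (rd in names(res$tables)) {
  rows <- sum(vapply(res$tables[[rd]], nrow, 1L))
  cat("reader", rd, ":", length(res$tables[[rd]]), "tables,", rows,
      "feature rows -> results/run/repeatability_reader", rd, "/\n", sep = "")
}
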