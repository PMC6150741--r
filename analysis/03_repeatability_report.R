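#!/usr/bin/env Rscript
# Summarize the per-reader repeatability tables: reliability-class counts
# and median wCV per feature class, contrasting global (histogram, fractal)
# against local-regional (GLCM, GLDM, NGTDM, run-length, zone-size)
# features.

library(texrep)

run_dir <- "results/run"
if (!dir.exists(run_dir)) stop("run analysis/02_extract_features.R first")

reg <- feature_registry()
summaries <- list()
for (rd in c(1, 2)) {
  rdir <- file.path(run_dir, paste0("repeatability_reader", rd))
  if (!dir.exists(rdir)) next
  tabs <- do.call(rbind, lapply(list.files(rdir, full.names = TRUE),
                                read.csv))
  tabs$scope <- reg$scope[match(tabs$feature_name, reg$name)]
  by_class <- aggregate(wcv_percent ~ class, tabs[tabs$wcv_interpretable, ],
                        median)
  names(by_class)[2] <- "median_wcv_percent"
  by_class$reader <- rd
  summaries[[length(summaries) + 1]] <- by_class

  cat("\n== reader", rd, "==\n")
  print(table(tabs$reliability_class[tabs$wcv_interpretable]))
  glob <- median(tabs$wcv_percent[tabs$scope == "global" &
                                    tabs$wcv_interpretable])
  loc <- median(tabs$wcv_percent[tabs$scope == "local-regional" &
                                   tabs$wcv_interpretable])
  cat(sprintf("median wCV: global %.1f%% vs local-regional %.1f%%\n",
              glob, loc))
}

summary_df <- do.call(rbind, summaries)
write.csv(summary_df, "results/class_summary.csv", row.names = FALSE)
cat("\nwrote results/class_summary.csv\n")
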