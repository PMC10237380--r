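#!/usr/bin/env Rscript
# Stage 2: spatial-scale screening of juniper metrics.
#
# Fits univariate habitat-use models for percent juniper cover at each
# measured radius (plus the >20%-category proportion and the clustering
# index at 100 m), ranks them by PSIS-LOO elpd, and carries the selected
# metric forward.  Writes results/scale_screening.csv.

library(autocc)

seed <- as.integer(Sys.getenv("AUTOCC_SEED", "4242"))
bundle_dir <- "results/bundle"
covs <- utils::read.csv(file.path(bundle_dir, "covariates.csv"))
y <- detection_history_from_df(utils::read.csv(file.path(bundle_dir, "detections.csv")))

metrics <- grep("^juniper_", names(covs), value = TRUE)
metrics <- c(metrics, intersect(c("p_gt20", "clustering"), names(covs)))
message("Screening metrics: ", paste(metrics, collapse = ", "))

sc <- scale_screening(y, covs, metrics, det = ~tri,
                      chains = 3, iter = 1500, warmup = 750,
                      seed = child_seed(seed, 21L))
utils::write.csv(sc$table, "results/scale_screening.csv", row.names = FALSE)
print(sc$table[, c("metric", "elpd", "delta_elpd", "delta_se", "beta",
                   "lo90", "hi90", "direction")], digits = 3)
message("Selected metric: ", sc$selected)
writeLines(sc$selected, "results/selected_metric.txt")
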