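#!/usr/bin/env Rscript
# Step 4: incremental-value performance report per comparator score:
# 10-year c-statistics, AIC, IDI and continuous NRI for Models C and D
# versus Model A, and collinearity diagnostics.
#
# Usage: Rscript analysis/04_performance.R   (after 03_models.R)

source("analysis/_common.R")

for (nm in names(scores)) {
  nested <- readRDS(file.path("results", paste0(nm, "_nested.rds")))
  perf <- performance_report(nested)
  cat("\n==", nm, "==\n")
  print(perf)
  jsonlite::write_json(
    list(outcome = perf$outcome,
         c_stat = lapply(perf$c_stat, function(x) x[c("c", "lower", "upper")]),
         aic = as.list(perf$aic),
         interaction_p = perf$interaction_p,
         comparisons = lapply(perf$comparisons, function(r)
           list(idi = r$idi$idi, nri_overall = r$nri$overall,
                nri_event = r$nri$event, nri_nonevent = r$nri$nonevent)),
         vif = perf$vif),
    file.path("results", paste0(nm, "_performance.json")),
    auto_unbox = TRUE, digits = NA)
}
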