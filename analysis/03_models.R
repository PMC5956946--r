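#!/usr/bin/env Rscript
# Step 3: fit the nested Model A-D comparisons (risk score alone, MetS Z
# alone, both, both plus interaction; all site-adjusted) for each
# comparator score and print the paper-style model summaries.
#
# Usage: Rscript analysis/03_models.R   (after 02_score.R)

source("analysis/_common.R")

for (nm in names(scores)) {
  sd_ <- score_data(nm)
  nested <- run_nested(sd_$data, sd_$col, "mets_z", outcome = outcomes[[nm]])
  saveRDS(nested, file.path("results", paste0(nm, "_nested.rds")))

  cat("\n==", nm, "(", outcomes[[nm]], ") ==\n")
  for (m in c("A", "B", "C", "D")) {
    fit <- nested[[m]]
    main <- fit$ratio[!grepl("^site", fit$ratio$term), , drop = FALSE]
    cat(sprintf("  Model %s  AIC %.1f  logL %.1f\n", m, fit$aic, fit$loglik))
    for (i in seq_len(nrow(main))) {
      cat(sprintf("    %-14s %5.2f (%.2f, %.2f)\n", main$term[i],
                  main$estimate[i], main$lower[i], main$upper[i]))
    }
  }
  cat(sprintf("  interaction p = %.3g\n", nested$interaction_p))
}
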