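#!/usr/bin/env Rscript
# Step 5: per-quintile MetS severity effects — does the MetS Z add hazard
# information uniformly across the comparator-score distribution, or
# mostly where the score itself calls risk low? Writes a forest-style SVG
# plot and a TSV sidecar per score.
#
# Usage: Rscript analysis/05_interactions.R   (after 02_score.R)

source("analysis/_common.R")

for (nm in names(scores)) {
  sd_ <- score_data(nm)
  eff <- tryCatch(
    per_quintile_mets_effect(sd_$data, sd_$col$raw, sd_$data$mets_z,
                             outcomes[[nm]]),
    error = function(e) {
      cat("\n==", nm, "==\n  skipped:", conditionMessage(e), "\n")
      NULL
    })
  if (is.null(eff)) next
  plot_quintile_effects(eff, file.path("results", paste0(nm, "_quintiles.svg")))
  cat("\n==", nm, "(", outcomes[[nm]], ") ==\n")
  print(eff[, c("quintile", "estimate", "lower", "upper", "n", "n_events")],
        row.names = FALSE)
}
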