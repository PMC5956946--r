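utils::globalVariables(c("quintile", "estimate", "lower", "upper"))

#' Prepare the analytic sample for one outcome
#'
#' Applies the baseline exclusions, scores MetS severity per subgroup, and
#' attaches the outcome columns: for CHD, `time` (days) and `event`; for
#' T2DM, the dichotomous 10-year `outcome` (participants without usable
#' follow-up are dropped, with a notice in the returned tally).
#'
#' @param cohort a raw `cohort` object.
#' @param loadings optional per-subgroup MetS loadings (fitted in-sample
#'   when `NULL`).
#' @return list with `data` (analytic data frame incl. `mets_z`), `tally`,
#'   `loadings`.
#' @export
prepare_analytic <- function(cohort, loadings = NULL) {
  ex <- apply_exclusions(cohort)
  ana <- ex$cohort
  sc <- score_mets_cohort(ana, loadings)
  df <- ana$participants
  df$mets_z <- sc$score
  df$time <- df$time_to_chd
  df$event <- df$chd_event
  df$t2dm_10yr <- t2dm_10yr_outcome(ana)
  list(data = df, tally = ex$tally, loadings = sc$loadings, cohort = ana)
}

#' Run the full added-value analysis pipeline
#'
#' Orchestrates simulate / score / evaluate / interact for a set of
#' comparator risk scores: generates (or loads) the cohort, applies the
#' exclusion rules, computes the MetS severity Z and each comparator
#' score, fits the nested Model A-D comparisons with site adjustment,
#' computes the 10-year performance report, the per-quintile MetS effects,
#' and writes TSV/JSON outputs plus a provenance manifest. Deterministic
#' given seeds.
#'
#' @param config list with elements: `cohort` (a `cohort` object) or
#'   `sim_config` (a [sim_config()]); `scores`, a named list of
#'   `risk_score_spec`s; `outcomes`, named character vector mapping each
#'   score name to `"chd"` or `"t2dm"`; optional `loadings`; optional
#'   `horizon_days`; optional `seed`.
#' @param out_dir output directory (created); `NULL` to skip writing.
#' @return list of per-score results (`nested`, `performance`,
#'   `quintiles`), plus `tally`, `loadings`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", label, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("simulate", {
    if (!is.null(config$cohort)) config$cohort
    else if (!is.null(config$sim_config)) simulate_cohort(config$sim_config)
    else stop("config must name a cohort or a sim_config")
  })
  prep <- stage("score", prepare_analytic(cohort, config$loadings))
  df <- prep$data
  horizon <- if (is.null(config$horizon_days)) TEN_YEARS_DAYS else config$horizon_days

  results <- list()
  for (nm in names(config$scores)) {
    spec <- config$scores[[nm]]
    outc <- unname(config$outcomes[[nm]])
    res <- stage(paste0("evaluate:", nm), {
      col <- standardize_score(compute_score(df, spec))
      dat <- df
      if (outc == "t2dm") {
        dat <- dat[!is.na(dat$t2dm_10yr), , drop = FALSE]
        col_sub <- col
        keep <- !is.na(df$t2dm_10yr)
        col_sub$raw <- col$raw[keep]; col_sub$standardized <- col$standardized[keep]
        col <- col_sub
        dat$outcome <- dat$t2dm_10yr
      }
      if (is.null(dat$mets_z) || all(is.na(dat$mets_z))) {
        warning("no MetS column available: Models B-D skipped for ", nm)
        return(list(skipped = TRUE))
      }
      nested <- run_nested(dat, col, "mets_z", outcome = outc)
      perf <- performance_report(nested, horizon_days = horizon)
      # ordinal scores can tie at the quantile cuts; record the flag
      # instead of estimating merged bins
      quint <- tryCatch(
        suppressWarnings(per_quintile_mets_effect(dat, col$raw, dat$mets_z, outc)),
        error = function(e) {
          warning("quintile analysis flagged for ", nm, ": ",
                  conditionMessage(e))
          NULL
        })
      list(nested = nested, performance = perf, quintiles = quint,
           score_column = col, skipped = FALSE)
    })
    results[[nm]] <- res
  }

  manifest <- list(
    n_input = unname(prep$tally["n_input"]),
    n_analytic = unname(prep$tally["n_analytic"]),
    exclusion_tally = as.list(prep$tally),
    seed = if (!is.null(config$sim_config)) config$sim_config$seed else config$seed,
    horizon_days = horizon,
    scores = names(config$scores),
    package_version = as.character(utils::packageVersion("metsadd")))

  out <- list(results = results, tally = prep$tally,
              loadings = prep$loadings, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline outputs (tables, reports, plots, manifest)
#'
#' Emits, per score: a nested-model TSV shaped like the paper-style
#' summary tables (model rows, HR/OR, AIC, c, IDI, NRI columns), a JSON
#' performance report, a quintile-effect TSV and SVG plot; plus the
#' exclusion tally, MetS loadings YAML, and a JSON provenance manifest.
#'
#' @param pipeline result of [run_pipeline()].
#' @param out_dir directory to write into.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(pipeline$results)) {
    res <- pipeline$results[[nm]]
    if (isTRUE(res$skipped)) next
    utils::write.table(nested_table(res), file.path(out_dir, paste0(nm, "_models.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(performance_json(res$performance),
                         file.path(out_dir, paste0(nm, "_performance.json")),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$quintiles)) {
      plot_quintile_effects(res$quintiles,
                            file.path(out_dir, paste0(nm, "_quintiles.svg")))
    }
  }
  utils::write.csv(data.frame(step = names(pipeline$tally),
                              n = as.integer(pipeline$tally)),
                   file.path(out_dir, "exclusion_tally.csv"), row.names = FALSE)
  write_mets_loadings(pipeline$loadings, file.path(out_dir, "mets_loadings.yaml"))
  jsonlite::write_json(pipeline$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

nested_table <- function(res) {
  perf <- res$performance
  rows <- lapply(c("A", "B", "C", "D"), function(m) {
    fit <- res$nested[[m]]
    main <- fit$ratio[!grepl("^site", fit$ratio$term), , drop = FALSE]
    data.frame(model = m,
               terms = paste(sprintf("%s=%.3f (%.3f,%.3f)", main$term,
                                     main$estimate, main$lower, main$upper),
                             collapse = "; "),
               aic = fit$aic,
               c_stat = if (m %in% names(perf$c_stat)) perf$c_stat[[m]]$c else NA,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$idi_vs_A <- NA_real_; tab$nri_vs_A <- NA_real_
  tab$idi_vs_A[tab$model == "C"] <- perf$comparisons$C_vs_A$idi$idi
  tab$idi_vs_A[tab$model == "D"] <- perf$comparisons$D_vs_A$idi$idi
  tab$nri_vs_A[tab$model == "C"] <- perf$comparisons$C_vs_A$nri$overall
  tab$nri_vs_A[tab$model == "D"] <- perf$comparisons$D_vs_A$nri$overall
  tab
}

performance_json <- function(perf) {
  list(outcome = perf$outcome, horizon_days = perf$horizon_days,
       c_stat = lapply(perf$c_stat, function(x) x[c("c", "lower", "upper")]),
       aic = as.list(perf$aic),
       interaction_p = perf$interaction_p,
       comparisons = lapply(perf$comparisons, function(r) {
         list(method = r$method,
              idi = r$idi[c("idi", "lower", "upper")],
              nri = r$nri[c("overall", "overall_lower", "overall_upper",
                            "event", "event_lower", "event_upper",
                            "nonevent", "nonevent_lower", "nonevent_upper")])
       }),
       vif = perf$vif)
}
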