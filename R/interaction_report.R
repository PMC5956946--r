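#' Empirical quintile bins of a risk score
#'
#' Cuts a score at its empirical 20/40/60/80th percentiles. Values exactly
#' at a boundary fall in the lower quintile. Fewer than five distinct
#' boundary values flag the binning as degenerate.
#'
#' @param score numeric vector (n >= 5).
#' @return list with `assignment` (integer 1-5), `boundaries` (the four
#'   interior cut points), `degenerate` (logical).
#' @export
quintile_bins <- function(score) {
  if (length(score) < 5) stop("need at least 5 observations")
  bounds <- stats::quantile(score, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  brk <- c(-Inf, bounds, Inf)
  degenerate <- any(duplicated(bounds)) || length(unique(score)) < 5
  assignment <- as.integer(cut(score, breaks = unique(brk), right = TRUE))
  if (degenerate) {
    warning("degenerate quintile boundaries (duplicate cut points)")
  }
  list(assignment = assignment, boundaries = bounds, degenerate = degenerate)
}

#' Per-quintile MetS severity effect
#'
#' Fits the outcome model with MetS-by-quintile interactions (quintile
#' indicators, their interactions with the MetS severity Z, and study-site
#' adjustment) and returns the per-quintile hazard or odds ratio of MetS
#' severity per SD unit with 95% CIs. Quintiles with no events are
#' flagged rather than estimated.
#'
#' @param data analytic-sample data frame (with `site` and outcome
#'   columns).
#' @param score numeric comparator risk score (raw scale).
#' @param mets numeric MetS severity Z column.
#' @param outcome `"chd"` or `"t2dm"`.
#' @return object of class `quintile_effects`: data frame with `quintile`,
#'   `lower_bound`, `upper_bound`, `estimate`, `lower`, `upper`,
#'   `n`, `n_events`, `flagged`; attributes carry the fit.
#' @export
per_quintile_mets_effect <- function(data, score, mets,
                                     outcome = c("chd", "t2dm")) {
  outcome <- match.arg(outcome)
  qb <- quintile_bins(score)
  if (qb$degenerate) stop("degenerate quintile binning: refusing to estimate")
  data$quintile <- factor(qb$assignment, levels = 1:5)
  data$mets <- if (is.character(mets)) data[[mets]] else mets
  data$site <- factor(data$site)
  site_term <- if (nlevels(data$site) > 1) "site" else NULL
  # one MetS slope per quintile: mets nested in quintile
  terms <- c("quintile", "quintile:mets", site_term)
  fit <- if (outcome == "chd") fit_cox(data, terms) else
    fit_logistic(data, terms, outcome = "outcome")
  ev <- if (outcome == "chd") data$event else data$outcome
  bounds <- c(-Inf, qb$boundaries, Inf)
  rows <- lapply(1:5, function(q) {
    term <- sprintf("quintile%d:mets", q)
    i <- match(term, fit$terms)
    n_ev <- sum(ev[data$quintile == q])
    data.frame(quintile = q, lower_bound = bounds[q], upper_bound = bounds[q + 1],
               estimate = exp(fit$coef[i]),
               lower = exp(fit$coef[i] - 1.96 * fit$se[i]),
               upper = exp(fit$coef[i] + 1.96 * fit$se[i]),
               n = sum(data$quintile == q), n_events = n_ev,
               flagged = n_ev < 1)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  attr(out, "outcome") <- outcome
  class(out) <- c("quintile_effects", "data.frame")
  out
}

#' Plot per-quintile MetS effects
#'
#' HR/OR per MetS severity SD by comparator-score quintile, on a log
#' scale with 95% CI whiskers. A sidecar TSV of the plotted values is
#' written next to the figure so the plot is testable without image
#' comparison.
#'
#' @param effects a `quintile_effects` object.
#' @param path output file (`.svg` or `.pdf`); sidecar TSV gets the same
#'   stem.
#' @return the ggplot object, invisibly.
#' @export
plot_quintile_effects <- function(effects, path = NULL) {
  df <- as.data.frame(effects)
  lab <- if (identical(attr(effects, "outcome"), "chd")) "HR" else "OR"
  df$quintile <- factor(df$quintile)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = quintile, y = estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lower, ymax = upper),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Risk-score quintile",
                  y = sprintf("%s per MetS severity SD (95%% CI)", lab)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    dev_fun <- if (grepl("\\.svg$", path)) grDevices::svg else grDevices::pdf
    dev_fun(path, width = 5, height = 4)
    print(gg)
    grDevices::dev.off()
    utils::write.table(df, sub("\\.[a-z]+$", ".tsv", path), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(gg)
}
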