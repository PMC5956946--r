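#' c-statistic (area under the ROC curve) for a binary outcome
#'
#' All-pairs concordance probability: among all event/non-event pairs, the
#' proportion where the event subject has the higher predicted risk, ties
#' counting one half. The 95% CI uses the DeLong placement-variance
#' estimator.
#'
#' @param p predicted risks.
#' @param y event indicator (logical or 0/1).
#' @return list with `c`, `se`, `lower`, `upper`, `n_event`, `n_nonevent`.
#' @export
c_statistic_binary <- function(p, y) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r_all <- rank(p)
  # placements: per-event (vs non-events) and per-non-event (vs events)
  v10 <- (r_all[y] - rank(p[y])) / n0
  v01 <- 1 - (r_all[!y] - rank(p[!y])) / n1
  cstat <- mean(v10)
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  se <- sqrt(s10 / n1 + s01 / n0)
  list(c = cstat, se = se,
       lower = max(0, cstat - 1.96 * se), upper = min(1, cstat + 1.96 * se),
       n_event = n1, n_nonevent = n0)
}

#' c-statistic for censored survival data at a fixed horizon
#'
#' Harrell-type concordance over usable pairs: pairs (i, j) with
#' `time_i < time_j`, subject i an observed event, and `time_i <= horizon`.
#' A pair is concordant when the earlier event has the higher predicted
#' risk; risk ties count one half. The optional CI is a seeded
#' nonparametric bootstrap.
#'
#' @param time,event follow-up times (> 0) and event indicators.
#' @param risk predicted risks (higher = earlier event expected).
#' @param horizon horizon in the same time unit as `time`.
#' @param ci compute a bootstrap CI.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list with `c`, `n_pairs`, and when `ci=TRUE` `lower`, `upper`.
#' @export
c_statistic_survival <- function(time, event, risk, horizon = Inf,
                                 ci = FALSE, B = 200, seed = 1) {
  if (any(time <= 0)) stop("times must be positive")
  est <- function(time, event, risk) {
    idx <- which(event & time <= horizon)
    conc <- 0; total <- 0
    for (i in idx) {
      later <- time > time[i]
      n_l <- sum(later)
      if (n_l == 0) next
      conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
      total <- total + n_l
    }
    if (total == 0) stop("no usable pairs")
    c(conc / total, total)
  }
  e <- est(time, event, risk)
  out <- list(c = e[1], n_pairs = e[2])
  if (ci) {
    set.seed(seed)
    n <- length(time)
    reps <- vapply(seq_len(B), function(b) {
      s <- sample.int(n, n, replace = TRUE)
      tryCatch(est(time[s], event[s], risk[s])[1], error = function(e) NA_real_)
    }, numeric(1))
    q <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out$lower <- q[1]; out$upper <- q[2]
  }
  out
}

#' Discrimination slope and integrated discrimination improvement (IDI)
#'
#' The discrimination slope is the mean predicted risk among events minus
#' the mean among non-events. The IDI is the difference in discrimination
#' slopes between the augmented and the base model; its CI uses the
#' standard paired-difference variance estimator on the per-subject risk
#' changes.
#'
#' @param p,p_old,p_new predicted risks.
#' @param y event indicator.
#' @param weights optional per-subject event-probability weights in
#'   `[0, 1]` (used by the survival extension); `y` is ignored when given.
#' @return `discrimination_slope()`: a number. `idi()`: list with `idi`,
#'   `se`, `lower`, `upper`, `slope_old`, `slope_new`.
#' @export
discrimination_slope <- function(p, y, weights = NULL) {
  w <- slope_weights(y, weights, length(p))
  sum(w * p) / sum(w) - sum((1 - w) * p) / sum(1 - w)
}

slope_weights <- function(y, weights, n) {
  if (!is.null(weights)) {
    stopifnot(all(weights >= 0 & weights <= 1))
    if (sum(weights) == 0 || sum(1 - weights) == 0) {
      stop("both outcome classes must be present")
    }
    return(weights)
  }
  y <- as.logical(y)
  if (!any(y) || all(y)) stop("both outcome classes must be present")
  as.numeric(y)
}

#' @rdname discrimination_slope
#' @export
idi <- function(p_old, p_new, y, weights = NULL) {
  w <- slope_weights(y, weights, length(p_old))
  d <- p_new - p_old
  slope_old <- discrimination_slope(p_old, weights = w, y = NULL)
  slope_new <- discrimination_slope(p_new, weights = w, y = NULL)
  est <- slope_new - slope_old
  # paired-difference variance of the weighted within-class means of d
  n1 <- sum(w); n0 <- sum(1 - w)
  m1 <- sum(w * d) / n1; m0 <- sum((1 - w) * d) / n0
  v1 <- sum(w * (d - m1)^2) / n1; v0 <- sum((1 - w) * (d - m0)^2) / n0
  se <- sqrt(v1 / n1 + v0 / n0)
  list(idi = est, se = se, lower = est - 1.96 * se, upper = est + 1.96 * se,
       slope_old = slope_old, slope_new = slope_new)
}

#' Continuous net reclassification improvement (NRI)
#'
#' The event NRI is the proportion of events whose predicted risk
#' increased under the new model minus the proportion whose risk
#' decreased; the non-event NRI is the proportion of non-events whose risk
#' decreased minus the proportion whose risk increased. The overall NRI is
#' their sum. Exact ties (`p_new == p_old`) count as neither direction.
#' CIs are asymptotic from the binomial variances of the two components.
#'
#' @param p_old,p_new predicted risks from the base and augmented model.
#' @param y event indicator.
#' @param weights optional event-probability weights (survival extension).
#' @return list with `overall`, `event`, `nonevent`, each with `se`,
#'   `lower`, `upper` suffixes.
#' @export
continuous_nri <- function(p_old, p_new, y, weights = NULL) {
  w <- slope_weights(y, weights, length(p_old))
  up <- as.numeric(p_new > p_old)
  down <- as.numeric(p_new < p_old)
  n1 <- sum(w); n0 <- sum(1 - w)
  p_up1 <- sum(w * up) / n1; p_dn1 <- sum(w * down) / n1
  p_up0 <- sum((1 - w) * up) / n0; p_dn0 <- sum((1 - w) * down) / n0
  ev <- p_up1 - p_dn1
  ne <- p_dn0 - p_up0
  se_ev <- sqrt(max(0, p_up1 + p_dn1 - ev^2) / n1)
  se_ne <- sqrt(max(0, p_up0 + p_dn0 - ne^2) / n0)
  se_all <- sqrt(se_ev^2 + se_ne^2)
  all_ <- ev + ne
  list(overall = all_, overall_se = se_all,
       overall_lower = all_ - 1.96 * se_all, overall_upper = all_ + 1.96 * se_all,
       event = ev, event_se = se_ev,
       event_lower = ev - 1.96 * se_ev, event_upper = ev + 1.96 * se_ev,
       nonevent = ne, nonevent_se = se_ne,
       nonevent_lower = ne - 1.96 * se_ne, nonevent_upper = ne + 1.96 * se_ne)
}

#' Kaplan-Meier event-probability weights at a horizon
#'
#' For the survival extensions of IDI/NRI, each subject receives an
#' estimated probability of being an event by the horizon: 1 for observed
#' events at or before the horizon, 0 for subjects followed event-free
#' beyond it, and for subjects censored before it the conditional
#' probability `1 - S(h)/S(c)` from the overall Kaplan-Meier curve.
#'
#' @param time,event follow-up data.
#' @param horizon evaluation horizon.
#' @return numeric weights in `[0, 1]`.
#' @export
km_event_weights <- function(time, event, horizon) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  S_at <- function(t) {
    # step function, S(0) = 1
    vapply(t, function(tt) {
      i <- findInterval(tt, sf$time)
      if (i == 0) 1 else sf$surv[i]
    }, numeric(1))
  }
  Sh <- S_at(horizon)
  w <- numeric(length(time))
  is_event <- event & time <= horizon
  beyond <- time > horizon
  cens <- !is_event & !beyond
  w[is_event] <- 1
  w[beyond] <- 0
  if (any(cens)) {
    Sc <- S_at(time[cens])
    w[cens] <- ifelse(Sc > 0, pmin(pmax(1 - Sh / Sc, 0), 1), 0)
  }
  if (all(w == 0)) stop("all subjects censored before the horizon")
  w
}

#' Survival extensions of IDI and continuous NRI at a fixed horizon
#'
#' Computes IDI and continuous NRI when the outcome is a censored event
#' time, evaluated at a fixed horizon. The default (`method = "km"`)
#' handles censoring through Kaplan-Meier estimation: the NRI components
#' use KM event probabilities estimated within the up/down
#' reclassification groups, and the IDI/slopes use per-subject KM
#' conditional event-probability weights, so censored-before-horizon
#' subjects contribute partially. With no censoring before the horizon
#' both reduce exactly to the binary statistics on horizon-dichotomized
#' outcomes. `method = "complete_case"` instead drops subjects censored
#' before the horizon.
#'
#' CIs are seeded nonparametric bootstrap when `ci = TRUE`, otherwise the
#' binary asymptotic formulas applied to the weighted counts (labelled
#' approximate).
#'
#' @param time,event follow-up data.
#' @param p_old,p_new model-based 10-year risks.
#' @param horizon evaluation horizon (same unit as `time`).
#' @param method `"km"` or `"complete_case"`.
#' @param ci bootstrap CIs.
#' @param B,seed bootstrap controls.
#' @return list with `idi`, `nri` (as the binary functions return),
#'   `method`, and `weights`.
#' @export
survival_idi_nri <- function(time, event, p_old, p_new, horizon,
                             method = c("km", "complete_case"),
                             ci = FALSE, B = 200, seed = 1) {
  method <- match.arg(method)
  core <- function(time, event, p_old, p_new) {
    if (method == "complete_case") {
      keep <- event & time <= horizon | time > horizon
      y <- event[keep] & time[keep] <= horizon
      return(list(idi = idi(p_old[keep], p_new[keep], y),
                  nri = continuous_nri(p_old[keep], p_new[keep], y),
                  weights = as.numeric(y)))
    }
    w <- km_event_weights(time, event, horizon)
    id <- idi(p_old, p_new, y = NULL, weights = w)
    nri <- nri_km_groups(time, event, p_old, p_new, horizon)
    list(idi = id, nri = nri, weights = w)
  }
  out <- core(time, event, p_old, p_new)
  out$method <- method
  if (ci) {
    set.seed(seed)
    n <- length(time)
    reps <- t(vapply(seq_len(B), function(b) {
      s <- sample.int(n, n, replace = TRUE)
      r <- tryCatch(core(time[s], event[s], p_old[s], p_new[s]),
                    error = function(e) NULL)
      if (is.null(r)) rep(NA_real_, 4) else
        c(r$idi$idi, r$nri$overall, r$nri$event, r$nri$nonevent)
    }, numeric(4)))
    qs <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    out$idi$lower <- qs[1, 1]; out$idi$upper <- qs[2, 1]
    out$nri$overall_lower <- qs[1, 2]; out$nri$overall_upper <- qs[2, 2]
    out$nri$event_lower <- qs[1, 3]; out$nri$event_upper <- qs[2, 3]
    out$nri$nonevent_lower <- qs[1, 4]; out$nri$nonevent_upper <- qs[2, 4]
  }
  out
}

# NRI with event probabilities estimated by Kaplan-Meier within the
# up / down / tie reclassification groups (Pencina-style survival NRI):
#   event NRI    = [P(up) pE_up - P(down) pE_dn] / pE
#   nonevent NRI = [P(down)(1 - pE_dn) - P(up)(1 - pE_up)] / (1 - pE)
nri_km_groups <- function(time, event, p_old, p_new, horizon) {
  n <- length(time)
  grp <- ifelse(p_new > p_old, "up", ifelse(p_new < p_old, "down", "tie"))
  pE_in <- function(idx) {
    if (!length(idx)) return(0)
    mean(km_event_weights_safe(time[idx], event[idx], horizon))
  }
  pE_all <- pE_in(seq_len(n))
  if (pE_all <= 0 || pE_all >= 1) stop("degenerate event probability at horizon")
  p_up <- mean(grp == "up"); p_dn <- mean(grp == "down")
  pE_up <- pE_in(which(grp == "up")); pE_dn <- pE_in(which(grp == "down"))
  ev <- (p_up * pE_up - p_dn * pE_dn) / pE_all
  ne <- (p_dn * (1 - pE_dn) - p_up * (1 - pE_up)) / (1 - pE_all)
  n1 <- n * pE_all; n0 <- n * (1 - pE_all)
  # approximate binomial-form SEs on the KM-weighted proportions
  pu1 <- p_up * pE_up / pE_all; pd1 <- p_dn * pE_dn / pE_all
  pu0 <- p_up * (1 - pE_up) / (1 - pE_all); pd0 <- p_dn * (1 - pE_dn) / (1 - pE_all)
  se_ev <- sqrt(max(0, pu1 + pd1 - ev^2) / n1)
  se_ne <- sqrt(max(0, pd0 + pu0 - ne^2) / n0)
  se_all <- sqrt(se_ev^2 + se_ne^2)
  all_ <- ev + ne
  list(overall = all_, overall_se = se_all,
       overall_lower = all_ - 1.96 * se_all, overall_upper = all_ + 1.96 * se_all,
       event = ev, event_se = se_ev,
       event_lower = ev - 1.96 * se_ev, event_upper = ev + 1.96 * se_ev,
       nonevent = ne, nonevent_se = se_ne,
       nonevent_lower = ne - 1.96 * se_ne, nonevent_upper = ne + 1.96 * se_ne)
}

km_event_weights_safe <- function(time, event, horizon) {
  tryCatch(km_event_weights(time, event, horizon),
           error = function(e) rep(0, length(time)))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R_j^2)` from regressing covariate j on the remaining
#' covariates. Values above 10 flag severe collinearity; rank-deficient
#' designs yield infinite VIF, also flagged.
#'
#' @param design numeric matrix or data frame of covariates (>= 2 columns).
#' @return data frame with `term`, `vif`, `severe`.
#' @export
vif <- function(design) {
  X <- as.matrix(as.data.frame(design))
  if (ncol(X) < 2) stop("need at least 2 covariates")
  out <- data.frame(term = colnames(X), vif = NA_real_, severe = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    fitj <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fitj$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    out$vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    out$severe[j] <- out$vif[j] > 10
  }
  out
}

#' Full performance report for a nested comparison at 10 years
#'
#' Assembles c-statistics (old/new), discrimination slopes, IDI, and
#' continuous NRI — with event/non-event decomposition — for Model C vs A
#' and Model D vs A, plus per-model AIC and the VIFs of Model C's design.
#' Survival outcomes use the horizon-restricted concordance and the
#' KM-based IDI/NRI extensions.
#'
#' @param nested a `nested_comparison` from [run_nested()].
#' @param horizon_days evaluation horizon.
#' @param method censoring handling for survival IDI/NRI.
#' @param ci_boot bootstrap CIs for the survival statistics.
#' @param B,seed bootstrap controls.
#' @return object of class `performance_report`.
#' @export
performance_report <- function(nested, horizon_days = TEN_YEARS_DAYS,
                               method = "km", ci_boot = FALSE, B = 200,
                               seed = 1) {
  pred <- nested_predictions(nested, horizon_days)
  data <- nested$data
  comparisons <- list(C_vs_A = c("p_A", "p_C"), D_vs_A = c("p_A", "p_D"))
  res <- list()
  if (nested$outcome == "chd") {
    cs <- lapply(c(A = "p_A", C = "p_C", D = "p_D"), function(col)
      c_statistic_survival(data$time, data$event, pred[[col]], horizon_days))
    for (cmp in names(comparisons)) {
      po <- pred[[comparisons[[cmp]][1]]]; pn <- pred[[comparisons[[cmp]][2]]]
      res[[cmp]] <- survival_idi_nri(data$time, data$event, po, pn,
                                     horizon_days, method = method,
                                     ci = ci_boot, B = B, seed = seed)
    }
  } else {
    y <- data$outcome
    cs <- lapply(c(A = "p_A", C = "p_C", D = "p_D"), function(col)
      c_statistic_binary(pred[[col]], y))
    for (cmp in names(comparisons)) {
      po <- pred[[comparisons[[cmp]][1]]]; pn <- pred[[comparisons[[cmp]][2]]]
      res[[cmp]] <- list(idi = idi(po, pn, y),
                         nri = continuous_nri(po, pn, y), method = "binary")
    }
  }
  vifs <- vif(data.frame(score = data$score_display, mets = data$mets))
  structure(list(outcome = nested$outcome, c_stat = cs,
                 comparisons = res,
                 aic = c(A = nested$A$aic, B = nested$B$aic, C = nested$C$aic,
                         D = nested$D$aic),
                 interaction_p = nested$interaction_p, vif = vifs,
                 horizon_days = horizon_days),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>", x$outcome, "at", x$horizon_days, "days\n")
  cat(sprintf("  c: A=%.3f C=%.3f D=%.3f\n", x$c_stat$A$c, x$c_stat$C$c,
              x$c_stat$D$c))
  cat(sprintf("  AIC: A=%.1f B=%.1f C=%.1f D=%.1f  (interaction p=%.3g)\n",
              x$aic["A"], x$aic["B"], x$aic["C"], x$aic["D"], x$interaction_p))
  for (cmp in names(x$comparisons)) {
    r <- x$comparisons[[cmp]]
    cat(sprintf("  %s: IDI=%.4f (%.4f, %.4f)  NRI=%.3f [event %.3f, non-event %.3f]\n",
                cmp, r$idi$idi, r$idi$lower, r$idi$upper,
                r$nri$overall, r$nri$event, r$nri$nonevent))
  }
  invisible(x)
}
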