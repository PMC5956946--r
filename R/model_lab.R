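#' Fitted risk model (Cox or logistic) with a uniform contract
#'
#' `fit_cox()` maximizes the Cox partial likelihood (Efron tie handling by
#' default, Breslow by flag); `fit_logistic()` fits a binomial GLM by
#' iteratively reweighted least squares. Both return a `model_fit` carrying
#' coefficients, model-based covariance, log-likelihood, `AIC = 2k -
#' 2 logL`, and HR/OR with Wald 95% CIs.
#'
#' @param data data frame holding outcome and covariates.
#' @param terms character vector of covariate names (the design; factors
#'   expand to indicator columns with the first level as reference).
#' @param time,event column names of the follow-up time and event
#'   indicator (Cox).
#' @param outcome column name of the binary outcome (logistic).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `model_fit`.
#' @export
fit_cox <- function(data, terms, time = "time", event = "event",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_design(data, terms)
  if (any(data[[time]] <= 0)) stop("non-positive follow-up times")
  fml <- stats::reformulate(terms,
                            response = sprintf("survival::Surv(%s, %s)", time, event))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties,
                    control = survival::coxph.control(eps = 1e-10, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        stop("monotone partial likelihood / non-convergence: ", conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design in Cox fit")
  new_model_fit(fit, family = "cox", ties = ties,
                logl = fit$loglik[2], k = length(stats::coef(fit)),
                n = fit$n)
}

#' @rdname fit_cox
#' @export
fit_logistic <- function(data, terms, outcome = "outcome") {
  check_design(data, terms)
  fml <- stats::reformulate(terms, response = outcome)
  fit <- stats::glm(fml, data = data, family = stats::binomial())
  if (!fit$converged) stop("logistic fit did not converge")
  p <- stats::fitted(fit)
  if (any(p > 1 - 1e-10) || any(p < 1e-10)) {
    warning("fitted probabilities numerically 0 or 1: possible separation")
  }
  new_model_fit(fit, family = "logistic", ties = NA_character_,
                logl = as.numeric(stats::logLik(fit)),
                k = length(stats::coef(fit)), n = stats::nobs(fit))
}

check_design <- function(data, terms) {
  for (tm in terms) {
    nm <- all.vars(stats::reformulate(tm))
    if (!all(nm %in% names(data))) stop("missing covariate: ", tm)
  }
  num <- terms[vapply(terms, function(tm) {
    v <- all.vars(stats::reformulate(tm))
    length(v) == 1 && v %in% names(data) && is.numeric(data[[v]])
  }, logical(1))]
  for (tm in num) {
    if (stats::sd(data[[all.vars(stats::reformulate(tm))]]) == 0) {
      stop("degenerate (constant) covariate: ", tm)
    }
  }
  invisible(TRUE)
}

new_model_fit <- function(fit, family, ties, logl, k, n) {
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  est <- exp(beta)
  lo <- exp(beta - 1.96 * se)
  hi <- exp(beta + 1.96 * se)
  structure(list(family = family, terms = names(beta), coef = beta,
                 vcov = V, se = se, loglik = logl, k = k,
                 aic = 2 * k - 2 * logl,
                 ratio = data.frame(term = names(beta), estimate = est,
                                    lower = lo, upper = hi,
                                    p = 2 * stats::pnorm(-abs(beta / se)),
                                    row.names = NULL),
                 n = n, ties = ties, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  lab <- if (x$family == "cox") "HR" else "OR"
  cat(sprintf("<model_fit:%s> n=%d logL=%.2f AIC=%.2f\n", x$family, x$n,
              x$loglik, x$aic))
  r <- x$ratio
  r$estimate <- sprintf("%.3f (%.3f, %.3f)", r$estimate, r$lower, r$upper)
  names(r)[2] <- sprintf("%s (95%% CI)", lab)
  print(r[, 1:2], row.names = FALSE)
  invisible(x)
}

#' Wald test of a single coefficient
#' @param fit a `model_fit`.
#' @param term coefficient name.
#' @return two-sided p-value.
#' @export
wald_p <- function(fit, term) {
  i <- match(term, fit$terms)
  if (is.na(i)) stop("no such term: ", term)
  z <- fit$coef[i] / fit$se[i]
  2 * stats::pnorm(-abs(z))
}

#' Fit the nested Model A-D comparison
#'
#' Fits the four nested models on one analytic sample, all adjusted for
#' study site (fixed-effect indicators, first site as reference):
#' Model A, risk score only; Model B, MetS severity only; Model C, risk
#' score + MetS severity; Model D, Model C + the score-by-MetS interaction.
#' For display the risk score enters standardized when its standardize flag
#' is set; predicted risks for performance statistics are computed from
#' refits on the original scale via [nested_predictions()].
#'
#' @param data analytic-sample data frame containing `site` and the outcome
#'   columns.
#' @param score a `score_column` (see [compute_score()]), or the name of a
#'   numeric column of `data`.
#' @param mets numeric MetS severity column (or name of one).
#' @param outcome `"chd"` (Cox on `time`/`event` columns) or `"t2dm"`
#'   (logistic on `outcome` column).
#' @param ... passed on to the fitting function.
#' @return object of class `nested_comparison`: fits `A`-`D`, the
#'   interaction Wald p, and the prepared data.
#' @export
run_nested <- function(data, score, mets, outcome = c("chd", "t2dm"), ...) {
  outcome <- match.arg(outcome)
  if (inherits(score, "score_column")) {
    if (is.null(score$standardized)) score <- standardize_score(score)
    data$score_display <- score$standardized
    data$score_raw <- score$raw
  } else {
    data$score_display <- data$score_raw <- data[[score]]
  }
  data$mets <- if (is.character(mets)) data[[mets]] else mets
  data$score_x_mets <- data$score_display * data$mets
  data$site <- factor(data$site)
  site_term <- if (nlevels(data$site) > 1) "site" else NULL

  fitter <- if (outcome == "chd") fit_cox else fit_logistic
  fit_one <- function(terms, label) {
    tryCatch(fitter(data, c(terms, site_term), ...),
             error = function(e) stop("Model ", label, ": ", conditionMessage(e)))
  }
  A <- fit_one("score_display", "A")
  B <- fit_one("mets", "B")
  C <- fit_one(c("score_display", "mets"), "C")
  D <- fit_one(c("score_display", "mets", "score_x_mets"), "D")
  structure(list(A = A, B = B, C = C, D = D,
                 interaction_p = wald_p(D, "score_x_mets"),
                 outcome = outcome, data = data),
            class = "nested_comparison")
}

#' Predicted 10-year risks from the nested models
#'
#' Recomputes Models A, C and D with the risk score on its original scale
#' and returns each participant's predicted 10-year outcome probability:
#' for Cox models `1 - S0(10y)^exp(LP)` with the Breslow baseline survival
#' from the fit; for logistic models the fitted probability.
#'
#' @param nested a `nested_comparison`.
#' @param horizon_days evaluation horizon (default 3652 days).
#' @return data frame with columns `p_A`, `p_C`, `p_D`.
#' @export
nested_predictions <- function(nested, horizon_days = TEN_YEARS_DAYS) {
  data <- nested$data
  data$score_display <- data$score_raw  # original scale for prediction
  data$score_x_mets <- data$score_raw * data$mets
  site_term <- if (nlevels(data$site) > 1) "site" else NULL
  term_sets <- list(A = "score_display", C = c("score_display", "mets"),
                    D = c("score_display", "mets", "score_x_mets"))
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (lab in names(term_sets)) {
    terms <- c(term_sets[[lab]], site_term)
    if (nested$outcome == "chd") {
      fit <- fit_cox(data, terms)
      out[[paste0("p_", lab)]] <- cox_risk_at(fit, data, horizon_days)
    } else {
      fit <- fit_logistic(data, terms)
      out[[paste0("p_", lab)]] <- stats::fitted(fit$fit)
    }
  }
  out
}

#' 10-year predicted risk from a fitted Cox model
#'
#' `1 - S0(t)^exp(LP)`, with `S0` the Breslow baseline survival of the
#' fitted model (at the mean covariate vector, rescaled to absolute zero).
#'
#' @param fit a `model_fit` of family `cox`.
#' @param newdata data to predict for.
#' @param horizon_days horizon in the time unit of the fit.
#' @return numeric predicted risks in (0,1).
#' @export
cox_risk_at <- function(fit, newdata, horizon_days = TEN_YEARS_DAYS) {
  stopifnot(fit$family == "cox")
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  H0 <- if (any(bh$time <= horizon_days)) {
    max(bh$hazard[bh$time <= horizon_days])
  } else 0
  lp <- drop(stats::predict(fit$fit, newdata = newdata, type = "lp",
                            reference = "zero"))
  1 - exp(-H0 * exp(lp))
}
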