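TEN_YEARS_DAYS <- 3652L  # leap-year-safe decade

#' Apply baseline exclusion filters
#'
#' Removes participants in the cohort-construction order used for the
#' analytic sample: race other than white/black, baseline T2DM, baseline
#' CHD, baseline stroke, missing MetS components, non-fasting labs, and no
#' T2DM follow-up data. A participant counts toward the first filter that
#' removes them.
#'
#' @param cohort a `cohort` object carrying the baseline flags.
#' @return list with `cohort` (the analytic sample) and `tally` (named
#'   integer vector of removals per step, plus `n_input`/`n_analytic`).
#' @export
apply_exclusions <- function(cohort) {
  df <- cohort$participants
  steps <- c(other_race = "flag_other_race",
             baseline_t2dm = "flag_baseline_t2dm",
             baseline_chd = "flag_baseline_chd",
             baseline_stroke = "flag_baseline_stroke",
             missing_components = "flag_missing_components",
             nonfasting = "flag_nonfasting",
             no_t2dm_followup = "flag_no_t2dm_followup")
  tally <- stats::setNames(integer(length(steps)), names(steps))
  keep <- rep(TRUE, nrow(df))
  for (s in names(steps)) {
    hit <- keep & as.logical(df[[steps[s]]])
    tally[s] <- sum(hit)
    keep <- keep & !hit
  }
  out <- list(participants = df[keep, , drop = FALSE],
              visits = cohort$visits[cohort$visits$participant_id %in%
                                       df$participant_id[keep], , drop = FALSE])
  attr(out, "config") <- attr(cohort, "config")
  class(out) <- "cohort"
  if (nrow(out$participants) == 0) warning("analytic sample is empty")
  list(cohort = out,
       tally = c(tally, n_input = nrow(df), n_analytic = sum(keep)))
}

#' Per-visit T2DM status under a cohort protocol
#'
#' Applies the visit-based diagnostic rule. Under the ARIC protocol a visit
#' is T2DM-positive when the participant self-reports a physician
#' diagnosis, has fasting glucose >= 126 mg/dL or non-fasting glucose
#' >= 200 mg/dL, or uses insulin/oral hypoglycemic medication. Under the
#' JHS protocol it is positive when fasting glucose >= 126 mg/dL, HbA1c
#' >= 6.5%, or diabetes medication was taken within 2 weeks of the visit
#' (encoded here as the visit's medication flag); self-report is ignored.
#'
#' @param visits data frame of visit records (see [simulate_cohort()] for
#'   the columns).
#' @param protocol `"ARIC"` or `"JHS"`, scalar or one per visit row.
#' @return logical vector, one status per visit row.
#' @export
t2dm_status <- function(visits, protocol) {
  if (length(protocol) == 1) protocol <- rep(protocol, nrow(visits))
  if (!all(protocol %in% c("ARIC", "JHS"))) stop("unknown protocol")
  aric <- protocol == "ARIC"
  glu_hit_aric <- ifelse(visits$fasting, visits$glucose >= 126,
                         visits$glucose >= 200)
  status_aric <- visits$self_report_diagnosis | glu_hit_aric |
    visits$on_diabetes_medication
  status_jhs <- (visits$fasting & visits$glucose >= 126) |
    visits$hba1c >= 6.5 | visits$on_diabetes_medication
  ifelse(aric, status_aric, status_jhs)
}

#' Dichotomous 10-year T2DM outcome
#'
#' A participant is a 10-year incident T2DM case when any follow-up visit
#' within 3652 days of baseline is T2DM-positive under their protocol.
#'
#' @param cohort a `cohort` object (visits plus per-participant protocol).
#' @return logical vector aligned to `cohort$participants`; `NA` for
#'   participants without follow-up visits.
#' @export
t2dm_10yr_outcome <- function(cohort) {
  v <- cohort$visits
  prot <- cohort$participants$protocol[match(v$participant_id,
                                             cohort$participants$participant_id)]
  status <- t2dm_status(v, prot) & v$days_since_baseline <= TEN_YEARS_DAYS
  pos_ids <- unique(v$participant_id[status])
  has_fu <- cohort$participants$participant_id %in% v$participant_id
  out <- cohort$participants$participant_id %in% pos_ids
  out[!has_fu] <- NA
  out
}

#' Censored CHD follow-up time
#'
#' Follow-up time is the minimum of days to the first CHD event, death
#' from other causes, last contact, and the administrative end of
#' follow-up; the event indicator is TRUE only when the CHD event attains
#' that minimum.
#'
#' @param event_day,death_day,last_contact_day days since baseline
#'   (`NA`/`Inf` when the event did not occur).
#' @param admin_end_day administrative censoring day.
#' @return data frame with `time` (days) and `event` (logical).
#' @export
chd_followup <- function(event_day, death_day = Inf, last_contact_day = Inf,
                         admin_end_day = Inf) {
  k <- max(length(event_day), length(death_day), length(last_contact_day),
           length(admin_end_day))
  ev <- rep_len(ifelse(is.na(event_day), Inf, event_day), k)
  de <- rep_len(ifelse(is.na(death_day), Inf, death_day), k)
  lc <- rep_len(ifelse(is.na(last_contact_day), Inf, last_contact_day), k)
  ad <- rep_len(ifelse(is.na(admin_end_day), Inf, admin_end_day), k)
  tm <- pmin(ev, de, lc, ad)
  if (any(!is.finite(tm))) stop("every participant needs at least one finite follow-up date")
  if (any(tm <= 0)) stop("non-positive follow-up time")
  data.frame(time = tm, event = ev <= pmin(de, lc, ad))
}

#' Declarative risk-score specification
#'
#' Constructs (or reads from YAML) the declarative description of a
#' published risk equation. Three outcome families are supported:
#' `survival10y` (Cox-type: 10-year risk `1 - S0^exp(LP - LPbar)`),
#' `logistic` (probability from intercept + terms), and `ordinal_points`
#' (integer points from covariate bins).
#'
#' Term lists are per-stratum: `terms` is a named list keyed by stratum
#' label (e.g. `"man"`, `"woman"`, or `"all"`), each a list of
#' `list(covariate=, transform=, coefficient=)` entries. For
#' `survival10y`, `s0` and `lp_mean` are per-stratum named numerics; for
#' `logistic`, `intercept` likewise. For `ordinal_points`, `points` is a
#' per-stratum list of `list(covariate=, breaks=, points=)` bins
#' (`cut(..., right = FALSE)` semantics) or
#' `list(covariate=, if_true=)` for logical covariates.
#'
#' @param name score name.
#' @param outcome_family one of `"survival10y"`, `"logistic"`,
#'   `"ordinal_points"`.
#' @param stratify_by covariate used to pick the stratum (`NULL` for a
#'   single `"all"` stratum).
#' @param terms,s0,lp_mean,intercept,points see Details.
#' @param standardize whether the score is Z-standardized in-sample before
#'   modelling.
#' @return object of class `risk_score_spec`.
#' @export
risk_score_spec <- function(name, outcome_family,
                            stratify_by = NULL, terms = NULL,
                            s0 = NULL, lp_mean = NULL, intercept = NULL,
                            points = NULL, standardize = TRUE) {
  outcome_family <- match.arg(outcome_family,
                              c("survival10y", "logistic", "ordinal_points"))
  if (outcome_family == "survival10y" && (is.null(s0) || is.null(lp_mean))) {
    stop("survival10y specs need s0 and lp_mean")
  }
  if (outcome_family == "logistic" && is.null(intercept)) {
    stop("logistic specs need an intercept")
  }
  if (outcome_family == "ordinal_points" && is.null(points)) {
    stop("ordinal_points specs need binning rules")
  }
  structure(list(name = name, outcome_family = outcome_family,
                 stratify_by = stratify_by, terms = terms, s0 = s0,
                 lp_mean = lp_mean, intercept = intercept, points = points,
                 standardize = standardize),
            class = "risk_score_spec")
}

#' @rdname risk_score_spec
#' @param path YAML file path.
#' @export
read_risk_score_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(risk_score_spec, raw)
}

#' @rdname risk_score_spec
#' @param spec a `risk_score_spec`.
#' @export
write_risk_score_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

spec_stratum <- function(spec, df) {
  if (is.null(spec$stratify_by)) rep("all", nrow(df))
  else as.character(df[[spec$stratify_by]])
}

eval_terms <- function(terms, df) {
  lp <- numeric(nrow(df))
  for (tm in terms) {
    if (!tm$covariate %in% names(df)) stop("missing covariate: ", tm$covariate)
    x <- df[[tm$covariate]]
    if (is.logical(x)) x <- as.numeric(x)
    tr <- if (is.null(tm$transform)) "identity" else tm$transform
    if (tr == "log") {
      if (any(x <= 0)) stop("log transform of non-positive ", tm$covariate)
      x <- log(x)
    } else if (tr != "identity") stop("unknown transform: ", tr)
    lp <- lp + tm$coefficient * x
  }
  lp
}

eval_points <- function(rules, df) {
  pts <- integer(nrow(df))
  for (r in rules) {
    x <- df[[r$covariate]]
    if (is.null(x)) stop("missing covariate: ", r$covariate)
    if (!is.null(r$if_true)) {
      pts <- pts + ifelse(as.logical(x), as.integer(r$if_true), 0L)
    } else {
      bin <- findInterval(x, r$breaks)  # breaks define left-closed bins
      pts <- pts + as.integer(r$points[bin + 1L])
    }
  }
  pts
}

#' Compute a comparator risk score over a cohort
#'
#' Deterministically evaluates a [risk_score_spec()]: the `survival10y`
#' family returns predicted 10-year risk `1 - S0^exp(LP - LPbar)`, the
#' `logistic` family a probability, and `ordinal_points` an integer score.
#'
#' @param cohort `cohort` object or participants data frame.
#' @param spec a `risk_score_spec`.
#' @return list of class `score_column` with `raw`, and after
#'   [standardize_score()], `standardized` plus the sample constants used.
#' @export
compute_score <- function(cohort, spec) {
  df <- if (inherits(cohort, "cohort")) cohort$participants else cohort
  strat <- spec_stratum(spec, df)
  raw <- rep(NA_real_, nrow(df))
  for (s in unique(strat)) {
    idx <- strat == s
    sub <- df[idx, , drop = FALSE]
    if (spec$outcome_family == "ordinal_points") {
      raw[idx] <- eval_points(spec$points[[s]], sub)
    } else {
      lp <- eval_terms(spec$terms[[s]], sub)
      if (spec$outcome_family == "survival10y") {
        risk <- 1 - spec$s0[[s]]^exp(lp - spec$lp_mean[[s]])
        raw[idx] <- risk
      } else {
        raw[idx] <- stats::plogis(spec$intercept[[s]] + lp)
      }
    }
  }
  structure(list(name = spec$name, raw = raw, standardized = NULL,
                 mean = NA_real_, sd = NA_real_,
                 standardize_flag = spec$standardize),
            class = "score_column")
}

#' In-sample Z-standardization of a score column
#'
#' Converts raw scores to Z-scores over the analytic sample when the
#' spec's standardize flag is set; returns the raw column untouched (with
#' `standardized = raw`) when not, mirroring the treatment of ordinal
#' scores.
#'
#' @param column a `score_column`.
#' @param flag override of the spec's standardize flag.
#' @return the `score_column` with `standardized`, `mean`, `sd` filled in.
#' @export
standardize_score <- function(column, flag = column$standardize_flag) {
  x <- column$raw
  if (!flag) {
    column$standardized <- x
    return(column)
  }
  if (length(x) < 2) stop("need n >= 2 to standardize")
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-SD score column cannot be standardized")
  column$standardized <- (x - m) / s
  column$mean <- m; column$sd <- s
  column
}
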