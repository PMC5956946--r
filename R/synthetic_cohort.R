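MET_COMPONENTS <- c("waist", "triglycerides", "hdl", "sbp", "glucose")
SUBGROUPS <- c("white_man", "white_woman", "black_man", "black_woman")

#' Simulation configuration for a synthetic ARIC/JHS-like cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' emulate the marginal structure of a large biracial US cohort of
#' middle-aged adults: per-subgroup means and SDs of the five metabolic
#' syndrome (MetS) components, a one-latent-factor correlation structure
#' among the components, Weibull proportional-hazards coronary heart
#' disease (CHD) events with administrative plus random censoring, and
#' visit-detected 10-year type 2 diabetes (T2DM) incidence driven by a
#' logistic model on baseline metabolic burden.
#'
#' Components are ordered waist circumference (cm), triglycerides (mg/dL),
#' HDL cholesterol (mg/dL), systolic blood pressure (mmHg), fasting glucose
#' (mg/dL). Triglycerides and insulin are simulated log-normally (both are
#' right-skewed in real cohorts); the remaining components are normal,
#' truncated at physiologic floors.
#'
#' @param n_participants number of participants to simulate.
#' @param subgroup_mix named proportions over the four sex-by-race
#'   subgroups; must sum to 1.
#' @param site_labels study-site labels; the last label is treated as the
#'   JHS-protocol site, the others as ARIC-protocol sites.
#' @param component_means,component_sds per-subgroup named lists of the five
#'   component means/SDs on the observed scale.
#' @param latent_loadings per-subgroup numeric vector of true factor
#'   loadings for the five components (HDL loading negative: low HDL is
#'   adverse).
#' @param noise_sds per-subgroup unique-variance SDs; `NULL` means
#'   `sqrt(1 - lambda^2)` so each standardized component has unit variance.
#' @param age_mean,age_sd per-subgroup age distribution (years).
#' @param smoking_prev,bp_treatment_prev,family_history_prev probabilities
#'   of current smoking, antihypertensive treatment, family history of
#'   diabetes.
#' @param total_chol_mean_sd length-2 numeric, total cholesterol mean and
#'   SD (mg/dL).
#' @param insulin_lognormal_params list with `meanlog`, `sdlog`, and
#'   `loading` (correlation of log-insulin with the latent MetS factor).
#' @param chd_hazard list: Weibull `shape`, `scale_years`, per-subgroup
#'   log-hazard `offset`, `risk_weights` defining the "true risk" linear
#'   predictor from standardized age, smoking, cholesterol and SBP, and the
#'   true log-hazard coefficients `beta_score`, `beta_mets`,
#'   `beta_interaction`.
#' @param t2dm_model list of true logistic coefficients for 10-year T2DM
#'   incidence: per-subgroup `intercept` plus `mets`, `glucose`, `bmi`,
#'   `age` (per SD) and `family_history`.
#' @param censoring list: `admin_years` administrative horizon and
#'   `dropout_rate` (per year) of exponential random censoring.
#' @param exclusion_prevs probabilities of the baseline exclusion flags
#'   (other race, prevalent T2DM/CHD/stroke, missing components,
#'   non-fasting labs, no T2DM follow-up).
#' @param visit_schedule list with `aric_days`, `jhs_days` (planned visit
#'   days) and `jitter_days`.
#' @param seed integer seed; identical seed and config give an identical
#'   cohort.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 13141,
                       subgroup_mix = c(white_man = 0.2972, white_woman = 0.3592,
                                        black_man = 0.1339, black_woman = 0.2097),
                       site_labels = c("A1", "A2", "A3", "A4", "JHS"),
                       component_means = default_component_means(),
                       component_sds = default_component_sds(),
                       latent_loadings = default_loadings(),
                       noise_sds = NULL,
                       age_mean = c(white_man = 54.5, white_woman = 53.8,
                                    black_man = 51.0, black_woman = 50.8),
                       age_sd = c(white_man = 5.7, white_woman = 5.6,
                                  black_man = 9.0, black_woman = 8.9),
                       smoking_prev = 0.25,
                       bp_treatment_prev = 0.25,
                       family_history_prev = 0.25,
                       total_chol_mean_sd = c(210, 40),
                       insulin_lognormal_params = list(meanlog = 2.12, sdlog = 0.6,
                                                       loading = 0.6),
                       chd_hazard = default_chd_hazard(),
                       t2dm_model = default_t2dm_model(),
                       censoring = list(admin_years = 24, dropout_rate = 0.0223),
                       exclusion_prevs = list(other_race = 0.003,
                                              baseline_t2dm = 0.02,
                                              baseline_chd = 0.05,
                                              baseline_stroke = 0.02,
                                              missing_components = 0.02,
                                              nonfasting = 0.02,
                                              no_t2dm_followup = 0.02),
                       visit_schedule = list(aric_days = c(1095, 2190, 3285),
                                             jhs_days = c(1825, 3285),
                                             jitter_days = 60),
                       seed = 1L) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      n_participants < 1) {
    stop("n_participants must be a positive count")
  }
  subgroup_mix <- subgroup_mix[SUBGROUPS]
  if (anyNA(subgroup_mix) || abs(sum(subgroup_mix) - 1) > 1e-6) {
    stop("subgroup_mix must be named over the four subgroups and sum to 1")
  }
  for (g in SUBGROUPS) {
    sds <- unlist(component_sds[[g]])
    if (any(sds <= 0)) stop("all component SDs must be > 0")
    lam <- latent_loadings[[g]]
    if (length(lam) != 5) stop("latent_loadings must have 5 entries per subgroup")
  }
  if (is.null(noise_sds)) {
    noise_sds <- lapply(latent_loadings, function(l) sqrt(pmax(0, 1 - l^2)))
  }
  if (censoring$admin_years < 10) {
    warning("administrative horizon below 10 years: 10-year statistics will be censored")
  }
  cfg <- list(n_participants = as.integer(n_participants),
              subgroup_mix = subgroup_mix, site_labels = site_labels,
              component_means = component_means, component_sds = component_sds,
              latent_loadings = latent_loadings, noise_sds = noise_sds,
              age_mean = age_mean, age_sd = age_sd,
              smoking_prev = smoking_prev, bp_treatment_prev = bp_treatment_prev,
              family_history_prev = family_history_prev,
              total_chol_mean_sd = total_chol_mean_sd,
              insulin_lognormal_params = insulin_lognormal_params,
              chd_hazard = chd_hazard, t2dm_model = t2dm_model,
              censoring = censoring, exclusion_prevs = exclusion_prevs,
              visit_schedule = visit_schedule, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_component_means <- function() {
  list(white_man   = c(waist = 98.9, triglycerides = 138.6, hdl = 43.6, sbp = 119.2, glucose = 100.8),
       white_woman = c(waist = 91.5, triglycerides = 119.1, hdl = 58.9, sbp = 116.0, glucose = 96.6),
       black_man   = c(waist = 97.4, triglycerides = 109.5, hdl = 48.6, sbp = 126.4, glucose = 95.2),
       black_woman = c(waist = 98.1, triglycerides = 95.0,  hdl = 57.1, sbp = 123.6, glucose = 93.2))
}

#' @rdname sim_config
#' @export
default_component_sds <- function() {
  list(white_man   = c(waist = 10.0, triglycerides = 84.6, hdl = 12.2, sbp = 15.3, glucose = 8.8),
       white_woman = c(waist = 13.6, triglycerides = 68.3, hdl = 16.8, sbp = 17.2, glucose = 8.6),
       black_man   = c(waist = 13.8, triglycerides = 77.8, hdl = 15.1, sbp = 18.4, glucose = 10.3),
       black_woman = c(waist = 16.3, triglycerides = 53.1, hdl = 16.1, sbp = 18.3, glucose = 10.5))
}

#' @rdname sim_config
#' @export
default_loadings <- function() {
  l <- c(waist = 0.7, triglycerides = 0.6, hdl = -0.5, sbp = 0.5, glucose = 0.6)
  list(white_man = l, white_woman = l, black_man = l, black_woman = l)
}

# Subgroup log-hazard offsets and logistic intercepts below are calibration
# constants fixed so that the default config reproduces the emulated study's
# 10-year cumulative incidences (CHD: 24.6/9.4/10.3/5.7%, overall ~13.2%;
# T2DM: 11.7/7.9/16.4/16.5%, overall ~12.0%).

#' @rdname sim_config
#' @export
default_chd_hazard <- function() {
  list(shape = 1.1, scale_years = 30,
       offset = c(white_man = -0.4806, white_woman = -1.5535,
                  black_man = -1.3613, black_woman = -1.9886),
       risk_weights = c(age = 0.40, smoking = 0.65, total_chol = 0.30, sbp = 0.25),
       beta_score = 1.0, beta_mets = 0.35, beta_interaction = 0.0)
}

#' @rdname sim_config
#' @export
default_t2dm_model <- function() {
  list(intercept = c(white_man = -2.7208, white_woman = -3.2122,
                     black_man = -2.1682, black_woman = -2.1485),
       mets = 0.7, glucose = 0.5, bmi = 0.3, age = 0.2, family_history = 0.5)
}

lognormal_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort with the generative structure assumed by the downstream
#' analysis: each participant's five MetS components arise from a single
#' latent metabolic-severity factor `f ~ N(0,1)` with subgroup-specific
#' loadings plus unique noise; CHD event times follow a Weibull
#' proportional-hazards model whose linear predictor combines a "true risk"
#' score (age, smoking, cholesterol, SBP) with the latent factor; 10-year
#' T2DM incidence follows the configured logistic model and is detected at
#' follow-up visits via the cohort's diagnostic rules.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cohort`: a list with `participants` (one row
#'   per participant) and `visits` (long format, keyed by `participant_id`
#'   and `visit_index`), carrying the config as an attribute. Columns
#'   prefixed `true_` are generative ground truth for recovery tests.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  set.seed(config$seed)
  # Draw order is fixed, block by block, so a given seed + config always
  # yields the identical cohort.
  subgroup <- sample(SUBGROUPS, n, replace = TRUE, prob = config$subgroup_mix)
  sex <- ifelse(grepl("man$", subgroup) & !grepl("woman$", subgroup), "man", "woman")
  race <- ifelse(grepl("^white", subgroup), "white", "black")

  n_sites <- length(config$site_labels)
  jhs_site <- config$site_labels[n_sites]
  aric_sites <- config$site_labels[-n_sites]
  site <- character(n)
  is_black <- race == "black"
  site[!is_black] <- sample(aric_sites, sum(!is_black), replace = TRUE)
  # black participants split between the JHS site and the ARIC sites
  site[is_black] <- ifelse(stats::runif(sum(is_black)) < 0.5, jhs_site,
                           sample(aric_sites, sum(is_black), replace = TRUE))
  protocol <- ifelse(site == jhs_site, "JHS", "ARIC")

  f <- stats::rnorm(n)  # latent MetS severity factor
  comp_z <- matrix(NA_real_, n, 5, dimnames = list(NULL, MET_COMPONENTS))
  for (k in seq_along(MET_COMPONENTS)) {
    eps <- stats::rnorm(n)
    for (g in SUBGROUPS) {
      idx <- subgroup == g
      lam <- config$latent_loadings[[g]][k]
      comp_z[idx, k] <- lam * f[idx] + config$noise_sds[[g]][k] * eps[idx]
    }
  }
  comp <- comp_z
  for (g in SUBGROUPS) {
    idx <- subgroup == g
    m <- config$component_means[[g]]
    s <- config$component_sds[[g]]
    for (k in seq_along(MET_COMPONENTS)) {
      nm <- MET_COMPONENTS[k]
      if (nm == "triglycerides") {
        lp <- lognormal_params(m[nm], s[nm])
        comp[idx, k] <- exp(lp$meanlog + lp$sdlog * comp_z[idx, k])
      } else {
        comp[idx, k] <- m[nm] + s[nm] * comp_z[idx, k]
      }
    }
  }
  # physiologic floors
  comp[, "waist"] <- pmax(comp[, "waist"], 50)
  comp[, "hdl"] <- pmax(comp[, "hdl"], 10)
  comp[, "sbp"] <- pmax(comp[, "sbp"], 70)
  comp[, "glucose"] <- pmax(comp[, "glucose"], 40)

  age <- stats::rnorm(n, config$age_mean[subgroup], config$age_sd[subgroup])
  age <- pmin(pmax(age, 21), 90)
  smoking <- stats::runif(n) < config$smoking_prev
  bp_treated <- stats::runif(n) < config$bp_treatment_prev
  family_history <- stats::runif(n) < config$family_history_prev
  total_chol <- pmax(stats::rnorm(n, config$total_chol_mean_sd[1],
                                  config$total_chol_mean_sd[2]), 90)
  bmi_z <- 0.7 * comp_z[, "waist"] + sqrt(1 - 0.49) * stats::rnorm(n)
  bmi_mean <- c(white_man = 27.2, white_woman = 26.1, black_man = 28.3, black_woman = 31.4)
  bmi_sd <- c(white_man = 3.8, white_woman = 5.0, black_man = 5.4, black_woman = 7.2)
  bmi <- pmax(bmi_mean[subgroup] + bmi_sd[subgroup] * bmi_z, 15)
  ip <- config$insulin_lognormal_params
  insulin <- exp(ip$meanlog + ip$sdlog *
                   (ip$loading * f + sqrt(1 - ip$loading^2) * stats::rnorm(n)))

  # CHD: Weibull PH.  eta combines the deterministic "true risk" linear
  # predictor with the latent factor and their interaction.
  hz <- config$chd_hazard
  age_z <- (age - 53.0) / 7.1
  chol_z <- (total_chol - config$total_chol_mean_sd[1]) / config$total_chol_mean_sd[2]
  sbp_z <- comp_z[, "sbp"]
  true_risk <- hz$risk_weights["age"] * age_z +
    hz$risk_weights["smoking"] * smoking +
    hz$risk_weights["total_chol"] * chol_z +
    hz$risk_weights["sbp"] * sbp_z
  eta <- hz$offset[subgroup] + hz$beta_score * true_risk +
    hz$beta_mets * f + hz$beta_interaction * true_risk * f
  u <- stats::runif(n)
  t_event <- hz$scale_years * (-log(u) / exp(eta))^(1 / hz$shape)
  t_admin <- config$censoring$admin_years
  t_drop <- if (config$censoring$dropout_rate > 0) {
    stats::rexp(n, config$censoring$dropout_rate)
  } else rep(Inf, n)
  t_obs <- pmin(t_event, t_admin, t_drop)
  chd_event <- t_event <= pmin(t_admin, t_drop)
  time_to_chd <- pmax(1L, as.integer(round(t_obs * 365.25)))

  # T2DM: Bernoulli draw from the configured 10-year logistic model; the
  # visit records are then constructed so the diagnostic rules detect
  # exactly the converters at their (uniform) conversion visit.
  tm <- config$t2dm_model
  glu_z <- comp_z[, "glucose"]
  logit_p <- tm$intercept[subgroup] + tm$mets * f + tm$glucose * glu_z +
    tm$bmi * bmi_z + tm$age * age_z + tm$family_history * family_history
  p_t2dm <- stats::plogis(logit_p)
  t2dm_10yr <- stats::runif(n) < p_t2dm

  visits <- build_visits(n, protocol, config$visit_schedule, comp[, "glucose"],
                         glu_z, f, t2dm_10yr)

  ep <- config$exclusion_prevs
  flag_other_race <- stats::runif(n) < ep$other_race
  race[flag_other_race] <- "other"
  flag_baseline_t2dm <- (comp[, "glucose"] >= 126) | (stats::runif(n) < ep$baseline_t2dm)
  flag_baseline_chd <- stats::runif(n) < ep$baseline_chd
  flag_baseline_stroke <- stats::runif(n) < ep$baseline_stroke
  flag_missing <- stats::runif(n) < ep$missing_components
  flag_nonfasting <- stats::runif(n) < ep$nonfasting
  flag_nofollowup <- stats::runif(n) < ep$no_t2dm_followup
  if (any(flag_missing)) {
    drop_k <- sample.int(5, sum(flag_missing), replace = TRUE)
    comp[cbind(which(flag_missing), drop_k)] <- NA_real_
  }
  visits <- visits[!(visits$participant_id %in% which(flag_nofollowup)), ,
                   drop = FALSE]

  participants <- data.frame(
    participant_id = seq_len(n), subgroup = subgroup, sex = sex, race = race,
    age = age, site = site, protocol = protocol,
    waist = comp[, "waist"], triglycerides = comp[, "triglycerides"],
    hdl = comp[, "hdl"], sbp = comp[, "sbp"], glucose = comp[, "glucose"],
    bmi = bmi, total_chol = total_chol, smoking = smoking,
    bp_treated = bp_treated, family_history_diabetes = family_history,
    insulin = insulin, time_to_chd = time_to_chd, chd_event = chd_event,
    flag_other_race = flag_other_race, flag_baseline_t2dm = flag_baseline_t2dm,
    flag_baseline_chd = flag_baseline_chd,
    flag_baseline_stroke = flag_baseline_stroke,
    flag_missing_components = flag_missing, flag_nonfasting = flag_nonfasting,
    flag_no_t2dm_followup = flag_nofollowup,
    true_f = f, true_risk = true_risk, true_t2dm_p = p_t2dm,
    true_t2dm_10yr = t2dm_10yr, true_chd_time = t_event,
    stringsAsFactors = FALSE)

  out <- list(participants = participants, visits = visits)
  attr(out, "config") <- config
  class(out) <- "cohort"
  out
}

build_visits <- function(n, protocol, schedule, glucose0, glu_z, f, t2dm) {
  id <- integer(0); vi <- integer(0); day <- numeric(0)
  is_jhs <- protocol == "JHS"
  plans <- list(ARIC = schedule$aric_days, JHS = schedule$jhs_days)
  for (p in c("ARIC", "JHS")) {
    idx <- which((protocol == "JHS") == (p == "JHS"))
    days <- plans[[p]]
    for (j in seq_along(days)) {
      id <- c(id, idx); vi <- c(vi, rep(j + 1L, length(idx)))
      day <- c(day, days[j] + stats::runif(length(idx), -schedule$jitter_days,
                                           schedule$jitter_days))
    }
  }
  day <- round(day)
  ord <- order(id, vi)
  id <- id[ord]; vi <- vi[ord]; day <- day[ord]
  m <- length(id)
  years <- day / 365.25

  # conversion day for converters: uniform between 6 months and their last
  # visit, so detection always occurs within follow-up
  last_day <- tapply(day, id, max)
  conv_day <- rep(Inf, n)
  conv <- which(t2dm)
  conv_day[conv] <- stats::runif(length(conv), 180,
                                 pmax(181, last_day[as.character(conv)]))
  diabetic <- day >= conv_day[id]

  fasting <- stats::runif(m) < 0.96
  # non-converters: mild upward drift with baseline burden, kept below the
  # diagnostic thresholds so the visit rules stay negative
  drift <- (0.3 + 0.2 * pmax(f[id], 0)) * years
  glu <- glucose0[id] + drift + stats::rnorm(m, 0, 4)
  glu <- ifelse(fasting, pmin(glu, 125), pmin(glu, 199))
  hba1c <- pmin(5.4 + 0.25 * glu_z[id] + stats::rnorm(m, 0, 0.25), 6.4)
  on_meds <- rep(FALSE, m)
  self_report <- rep(FALSE, m)
  # diabetic visits: labs above threshold, consistent with the protocol rule
  if (any(diabetic)) {
    dd <- which(diabetic)
    glu[dd] <- ifelse(fasting[dd], stats::runif(length(dd), 126, 200),
                      stats::runif(length(dd), 200, 320))
    hba1c[dd] <- stats::runif(length(dd), 6.5, 9.5)
    on_meds[dd] <- stats::runif(length(dd)) < 0.5
    self_report[dd] <- stats::runif(length(dd)) < 0.6
  }
  insulin_v <- exp(2.1 + 0.5 * stats::rnorm(m))
  data.frame(participant_id = id, visit_index = vi, days_since_baseline = day,
             fasting = fasting, glucose = pmax(glu, 40), hba1c = hba1c,
             on_diabetes_medication = on_meds,
             self_report_diagnosis = self_report, insulin = insulin_v,
             stringsAsFactors = FALSE)
}

#' True generative parameters of a simulation config
#'
#' Returns the ground-truth parameter record (factor loadings, CHD
#' log-hazard coefficients, T2DM logistic coefficients) for parameter
#' recovery tests, in a JSON-serializable form.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `latent_loadings`, `chd`, `t2dm`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  list(latent_loadings = lapply(config$latent_loadings, as.list),
       chd = list(shape = config$chd_hazard$shape,
                  scale_years = config$chd_hazard$scale_years,
                  offset = as.list(config$chd_hazard$offset),
                  risk_weights = as.list(config$chd_hazard$risk_weights),
                  beta_score = config$chd_hazard$beta_score,
                  beta_mets = config$chd_hazard$beta_mets,
                  beta_interaction = config$chd_hazard$beta_interaction),
       t2dm = list(intercept = as.list(config$t2dm_model$intercept),
                   mets = config$t2dm_model$mets,
                   glucose = config$t2dm_model$glucose,
                   bmi = config$t2dm_model$bmi, age = config$t2dm_model$age,
                   family_history = config$t2dm_model$family_history))
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes `participants.csv`, `visits.csv` and
#' `config.yaml` into `dir`; `read_cohort()` reads them back.
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `cohort` object.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  out <- list(participants = participants, visits = visits)
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    attr(out, "config") <- cfg
  }
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$participants), " participants, ",
      nrow(x$visits), " visit records\n", sep = "")
  invisible(x)
}
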