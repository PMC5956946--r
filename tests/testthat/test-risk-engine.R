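blank_cohort <- function(n) {
  df <- data.frame(participant_id = seq_len(n), subgroup = "white_man",
                   sex = "man", race = "white", site = "A1", protocol = "ARIC",
                   flag_other_race = FALSE, flag_baseline_t2dm = FALSE,
                   flag_baseline_chd = FALSE, flag_baseline_stroke = FALSE,
                   flag_missing_components = FALSE, flag_nonfasting = FALSE,
                   flag_no_t2dm_followup = FALSE)
  structure(list(participants = df,
                 visits = data.frame(participant_id = integer(0))),
            class = "cohort")
}

test_that("exclusions count each participant once, at the first filter", {
  co <- blank_cohort(100)
  co$participants$flag_baseline_t2dm[1:10] <- TRUE
  res <- apply_exclusions(co)
  expect_equal(nrow(res$cohort$participants), 90)
  expect_equal(unname(res$tally["baseline_t2dm"]), 10)
  expect_true(all(res$tally[c("other_race", "baseline_chd", "baseline_stroke",
                              "missing_components", "nonfasting",
                              "no_t2dm_followup")] == 0))

  # doubly-flagged participant counted at the earlier filter only
  co2 <- blank_cohort(10)
  co2$participants$flag_nonfasting[3] <- TRUE
  co2$participants$flag_missing_components[3] <- TRUE
  res2 <- apply_exclusions(co2)
  expect_equal(unname(res2$tally["missing_components"]), 1)
  expect_equal(unname(res2$tally["nonfasting"]), 0)

  # no flags: identity, and tally entries sum to removals
  res3 <- apply_exclusions(blank_cohort(25))
  expect_equal(nrow(res3$cohort$participants), 25)
  steps <- setdiff(names(res3$tally), c("n_input", "n_analytic"))
  expect_equal(sum(res2$tally[steps]),
               unname(res2$tally["n_input"] - res2$tally["n_analytic"]))
})

visit_row <- function(glucose, fasting = TRUE, hba1c = 5.5, meds = FALSE,
                      self_report = FALSE, day = 1000) {
  data.frame(participant_id = 1L, visit_index = 2L,
             days_since_baseline = day, fasting = fasting, glucose = glucose,
             hba1c = hba1c, on_diabetes_medication = meds,
             self_report_diagnosis = self_report, insulin = 8)
}

test_that("ARIC diagnostic rule reproduces the printed thresholds", {
  expect_true(t2dm_status(visit_row(126), "ARIC"))
  expect_false(t2dm_status(visit_row(125.9), "ARIC"))
  expect_true(t2dm_status(visit_row(200, fasting = FALSE), "ARIC"))
  expect_false(t2dm_status(visit_row(199, fasting = FALSE), "ARIC"))
  # non-fasting 126-199 is below the non-fasting cutoff
  expect_false(t2dm_status(visit_row(150, fasting = FALSE), "ARIC"))
  expect_true(t2dm_status(visit_row(90, meds = TRUE), "ARIC"))
  expect_true(t2dm_status(visit_row(90, self_report = TRUE), "ARIC"))
  # ARIC ignores HbA1c
  expect_false(t2dm_status(visit_row(90, hba1c = 8.0), "ARIC"))
})

test_that("JHS diagnostic rule reproduces the printed thresholds", {
  expect_true(t2dm_status(visit_row(126), "JHS"))
  expect_true(t2dm_status(visit_row(120, hba1c = 6.5), "JHS"))
  expect_false(t2dm_status(visit_row(120, hba1c = 6.49), "JHS"))
  expect_true(t2dm_status(visit_row(90, meds = TRUE), "JHS"))
  # JHS ignores self-report and non-fasting glucose elevation
  expect_false(t2dm_status(visit_row(90, self_report = TRUE), "JHS"))
  expect_false(t2dm_status(visit_row(210, fasting = FALSE, hba1c = 6.0), "JHS"))
  expect_error(t2dm_status(visit_row(90), "NHANES"), "unknown protocol")
})

test_that("10-year T2DM outcome respects the 3652-day window", {
  co <- blank_cohort(3)
  co$visits <- rbind(
    within(visit_row(130, day = 1100), participant_id <- 1L),
    within(visit_row(130, day = 4000), participant_id <- 2L),
    within(visit_row(100, day = 1100), participant_id <- 3L))
  out <- t2dm_10yr_outcome(co)
  expect_identical(out, c(TRUE, FALSE, FALSE))
  # boundary: day 3652 in, day 3653 out
  co$visits$days_since_baseline <- c(3652, 3653, 3652)
  co$visits$glucose <- c(130, 130, 130)
  expect_identical(t2dm_10yr_outcome(co), c(TRUE, FALSE, TRUE))
})

test_that("CHD follow-up takes the minimum date and flags events correctly", {
  r <- chd_followup(event_day = 500, last_contact_day = 900)
  expect_equal(r$time, 500); expect_true(r$event)
  r <- chd_followup(event_day = NA, death_day = 400)
  expect_equal(r$time, 400); expect_false(r$event)
  r <- chd_followup(event_day = NA, death_day = NA, last_contact_day = NA,
                    admin_end_day = 3000)
  expect_equal(r$time, 3000); expect_false(r$event)
  # event after censoring is censored
  r <- chd_followup(event_day = 1000, death_day = 800)
  expect_equal(r$time, 800); expect_false(r$event)
  expect_error(chd_followup(event_day = NA), "finite follow-up")
  expect_error(chd_followup(event_day = -5), "non-positive")
})

test_that("survival10y specs return bounded risks increasing in LP", {
  spec <- risk_score_spec("toy", "survival10y", stratify_by = NULL,
                          terms = list(all = list(list(covariate = "x",
                                                       transform = "identity",
                                                       coefficient = 0.5))),
                          s0 = list(all = 0.9), lp_mean = list(all = 0))
  df <- data.frame(x = seq(-4, 4, length.out = 50))
  risk <- compute_score(df, spec)$raw
  expect_true(all(risk > 0 & risk < 1))
  expect_true(all(diff(risk) > 0))
  # zero-coefficient spec: risk = 1 - S0 for everyone
  spec0 <- risk_score_spec("null", "survival10y", stratify_by = NULL,
                           terms = list(all = list(list(covariate = "x",
                                                        transform = "identity",
                                                        coefficient = 0))),
                           s0 = list(all = 0.9), lp_mean = list(all = 0))
  expect_equal(compute_score(df, spec0)$raw, rep(0.1, 50))
})

test_that("logistic and ordinal specs evaluate their stated forms", {
  spec <- risk_score_spec("logit0", "logistic", stratify_by = NULL,
                          terms = list(all = list(list(covariate = "x",
                                                       transform = "identity",
                                                       coefficient = 0))),
                          intercept = list(all = 0))
  expect_equal(compute_score(data.frame(x = 1:5), spec)$raw, rep(0.5, 5))

  pts <- risk_score_spec("pts", "ordinal_points", stratify_by = NULL,
                         points = list(all = list(
                           list(covariate = "age", breaks = c(40, 50, 60),
                                points = c(0, 1, 2, 3)),
                           list(covariate = "smoker", if_true = 1))))
  df <- data.frame(age = c(35, 40, 55, 70), smoker = c(FALSE, TRUE, TRUE, FALSE))
  got <- compute_score(df, pts)$raw
  expect_identical(got, c(0, 2, 3, 3))
  expect_true(all(got == as.integer(got)))
})

test_that("spec evaluation matches an independently coded brute force", {
  set.seed(31)
  df <- data.frame(sex = sample(c("man", "woman"), 50, TRUE),
                   age = runif(50, 45, 64), chol = runif(50, 150, 280),
                   sbp = runif(50, 95, 180), smoke = runif(50) < 0.3)
  spec <- risk_score_spec("fram_like", "survival10y", stratify_by = "sex",
    terms = list(man = list(list(covariate = "age", transform = "log", coefficient = 3.0),
                            list(covariate = "chol", transform = "log", coefficient = 1.1),
                            list(covariate = "smoke", transform = "identity", coefficient = 0.65)),
                 woman = list(list(covariate = "age", transform = "log", coefficient = 2.3),
                              list(covariate = "sbp", transform = "log", coefficient = 2.8))),
    s0 = list(man = 0.88, woman = 0.95),
    lp_mean = list(man = 13.5, woman = 14.2))
  got <- compute_score(df, spec)$raw
  manual <- vapply(seq_len(50), function(i) {
    if (df$sex[i] == "man") {
      lp <- 3.0 * log(df$age[i]) + 1.1 * log(df$chol[i]) + 0.65 * df$smoke[i]
      1 - 0.88^exp(lp - 13.5)
    } else {
      lp <- 2.3 * log(df$age[i]) + 2.8 * log(df$sbp[i])
      1 - 0.95^exp(lp - 14.2)
    }
  }, numeric(1))
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("shipped synthetic spec files parse and evaluate", {
  for (s in c("framingham", "ascvd", "bang", "schmidt")) {
    spec <- read_risk_score_spec(system.file("extdata",
                                             paste0(s, "_synthetic.yaml"),
                                             package = "metsadd"))
    expect_s3_class(spec, "risk_score_spec")
  }
  cfg <- sim_config(n_participants = 300, seed = 32)
  df <- prepare_analytic(simulate_cohort(cfg))$data
  fram <- read_risk_score_spec(system.file("extdata", "framingham_synthetic.yaml",
                                           package = "metsadd"))
  risk <- compute_score(df, fram)$raw
  expect_true(all(risk > 0 & risk < 1))
})

test_that("standardization yields Z-scores and rejects degenerate columns", {
  col <- structure(list(raw = rnorm(100, 5, 2), standardize_flag = TRUE),
                   class = "score_column")
  st <- standardize_score(col)
  expect_lt(abs(mean(st$standardized)), 1e-12)
  expect_equal(sd(st$standardized), 1, tolerance = 1e-12)
  # flag false: identity (ordinal convention)
  st2 <- standardize_score(col, flag = FALSE)
  expect_identical(st2$standardized, col$raw)
  const <- structure(list(raw = rep(3, 10), standardize_flag = TRUE),
                     class = "score_column")
  expect_error(standardize_score(const), "zero-SD")
  expect_error(compute_score(data.frame(y = 1),
                             risk_score_spec("m", "logistic", terms = list(
                               all = list(list(covariate = "x", coefficient = 1))),
                               intercept = list(all = 0))),
               "missing covariate")
})
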