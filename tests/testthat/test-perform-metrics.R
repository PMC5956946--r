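test_that("binary c-statistic equals exhaustive pair counting", {
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(50:300, 1)
    y <- runif(n) < 0.3
    if (!any(y) || all(y)) next
    p <- round(runif(n), 2)  # rounding forces ties
    got <- c_statistic_binary(p, y)$c
    expect_equal(got, oracle_c_binary(p, y), tolerance = 1e-10)
  }
  expect_equal(c_statistic_binary(c(0.9, 0.8, 0.1, 0.2),
                                  c(TRUE, TRUE, FALSE, FALSE))$c, 1.0)
  expect_error(c_statistic_binary(runif(5), rep(TRUE, 5)), "both outcome")
})

test_that("binary c-statistic is 0.5 under independence", {
  set.seed(52)
  y <- runif(10000) < 0.2
  p <- runif(10000)
  cs <- c_statistic_binary(p, y)
  expect_lt(abs(cs$c - 0.5), 0.02)
  expect_true(cs$lower < 0.5 && 0.5 < cs$upper)
})

test_that("survival c-statistic equals exhaustive usable-pair enumeration", {
  set.seed(53)
  for (rep in 1:4) {
    n <- 200
    d <- sim_ph_data(n, beta = 0.6, censor_rate = 0.08, scale = 12)
    d$time <- ceiling(d$time)  # day-type ties
    risk <- round(plogis(d$x + rnorm(n, 0, 0.5)), 2)
    h <- 10
    got <- c_statistic_survival(d$time, d$event, risk, h)$c
    expect_equal(got, oracle_c_survival(d$time, d$event, risk, h),
                 tolerance = 1e-10)
  }
})

test_that("survival c is 1 for a perfect marker and 0.5 for noise", {
  set.seed(54)
  t_ev <- sort(runif(100, 1, 9))
  expect_equal(c_statistic_survival(t_ev, rep(TRUE, 100), rev(seq(100)), 10)$c,
               1.0)
  d <- sim_ph_data(5000, beta = 0, censor_rate = 0.02, scale = 12)
  expect_lt(abs(c_statistic_survival(d$time, d$event, runif(5000), 10)$c - 0.5),
            0.02)
})

test_that("c-statistic is invariant to strictly increasing transforms", {
  set.seed(55)
  y <- runif(400) < 0.3
  p <- runif(400)
  base <- c_statistic_binary(p, y)$c
  expect_equal(c_statistic_binary(qlogis(p), y)$c, base, tolerance = 1e-12)
  expect_equal(c_statistic_binary(p^3, y)$c, base, tolerance = 1e-12)
})

test_that("discrimination slope, IDI and their identities check out", {
  set.seed(56)
  y <- runif(300) < 0.4
  p_old <- runif(300); p_new <- plogis(qlogis(p_old) + rnorm(300, 0, 0.3))
  expect_equal(discrimination_slope(p_old, y), oracle_slope(p_old, y),
               tolerance = 1e-12)
  r <- idi(p_old, p_new, y)
  expect_equal(r$idi, oracle_slope(p_new, y) - oracle_slope(p_old, y),
               tolerance = 1e-12)
  # antisymmetry
  expect_equal(idi(p_new, p_old, y)$idi, -r$idi, tolerance = 1e-14)
  # identity comparison
  expect_equal(idi(p_old, p_old, y)$idi, 0)
  # hand-arithmetic extreme: events 0.8 vs 0.5, non-events 0.2 vs 0.5
  y2 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(idi(rep(0.5, 4), c(0.8, 0.8, 0.2, 0.2), y2)$idi, 0.6)
})

test_that("continuous NRI matches sign-counting and decomposes exactly", {
  set.seed(57)
  for (rep in 1:4) {
    n <- 500
    y <- runif(n) < 0.35
    p_old <- round(runif(n), 2)
    p_new <- round(plogis(qlogis(pmin(pmax(p_old, 0.01), 0.99)) +
                            rnorm(n, 0, 0.4)), 2)
    r <- continuous_nri(p_old, p_new, y)
    o <- oracle_nri(p_old, p_new, y)
    expect_equal(r$overall, unname(o["overall"]), tolerance = 1e-10)
    expect_equal(r$event, unname(o["event"]), tolerance = 1e-10)
    expect_equal(r$nonevent, unname(o["nonevent"]), tolerance = 1e-10)
    expect_equal(r$overall, r$event + r$nonevent, tolerance = 1e-14)
  }
  # identical predictions: all zero
  y <- c(TRUE, FALSE, TRUE, FALSE)
  r0 <- continuous_nri(rep(0.3, 4), rep(0.3, 4), y)
  expect_equal(c(r0$overall, r0$event, r0$nonevent), c(0, 0, 0))
  # extreme: both events up, both non-events down
  r2 <- continuous_nri(c(0.5, 0.5, 0.5, 0.5), c(0.6, 0.7, 0.3, 0.2),
                       c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$overall, 2.0)
  expect_equal(r2$event, 1.0)
  expect_equal(r2$nonevent, 1.0)
})

test_that("KM weights are exact event indicators without pre-horizon censoring", {
  set.seed(58)
  n <- 300
  t_ev <- runif(n, 1, 20)
  event <- t_ev <= 12
  time <- ifelse(event, t_ev, 12)  # censored exactly at 12 > horizon 10
  time[event] <- pmin(time[event], 10 - 1e-9)
  w <- km_event_weights(time, event, horizon = 10)
  expect_identical(w, as.numeric(event))
})

test_that("survival IDI/NRI reduce exactly to the binary versions without censoring", {
  set.seed(59)
  n <- 400
  t_ev <- rexp(n, 0.08)
  event10 <- t_ev <= 10
  time <- ifelse(event10, t_ev, 11 + runif(n))
  event <- event10
  p_old <- runif(n); p_new <- plogis(qlogis(p_old) + rnorm(n, 0, 0.4))
  sv <- survival_idi_nri(time, event, p_old, p_new, horizon = 10)
  bin_idi <- idi(p_old, p_new, event10)
  bin_nri <- continuous_nri(p_old, p_new, event10)
  expect_equal(sv$idi$idi, bin_idi$idi, tolerance = 1e-12)
  expect_equal(sv$nri$overall, bin_nri$overall, tolerance = 1e-12)
  expect_equal(sv$nri$event, bin_nri$event, tolerance = 1e-12)
  expect_equal(sv$nri$nonevent, bin_nri$nonevent, tolerance = 1e-12)
  # complete-case fallback agrees too in this censoring-free setting
  cc <- survival_idi_nri(time, event, p_old, p_new, horizon = 10,
                         method = "complete_case")
  expect_equal(cc$idi$idi, bin_idi$idi, tolerance = 1e-12)
})

test_that("KM weighting diverges from complete-case as the censoring mechanism predicts", {
  # heavy early censoring concentrated in high-risk subjects: the pooled KM
  # assigns those censored subjects the population-average conditional risk,
  # which is lower than their true risk, so the KM-weighted event
  # probability must fall below the complete-case one; the closed-form
  # incidence from the generative exponential model brackets both.
  set.seed(60)
  n <- 4000
  x <- rnorm(n)
  rate <- 0.05 * exp(0.9 * x)
  t_ev <- rexp(n, rate)
  cens <- ifelse(x > 1, runif(n, 0.5, 3), 50)  # early dropout for high risk
  time <- pmin(t_ev, cens); event <- t_ev <= cens
  true_p10 <- mean(stats::pexp(10, rate))  # closed-form oracle
  w <- km_event_weights(time, event, 10)
  km_p10 <- mean(w)
  cc_keep <- (event & time <= 10) | time > 10
  cc_p10 <- mean(event[cc_keep] & time[cc_keep] <= 10)
  expect_lt(km_p10, cc_p10)   # predicted direction of divergence
  expect_lt(abs(km_p10 - true_p10), 0.1)
  expect_lt(abs(cc_p10 - true_p10), 0.1)

  # and the two estimators disagree on IDI/NRI under this mechanism while
  # agreeing when censoring is absent (reduction test above)
  p_old <- plogis(0.5 * x); p_new <- plogis(0.9 * x)
  km <- survival_idi_nri(time, event, p_old, p_new, 10, method = "km")
  cc <- survival_idi_nri(time, event, p_old, p_new, 10,
                         method = "complete_case")
  expect_false(isTRUE(all.equal(km$nri$event, cc$nri$event, tolerance = 1e-4)))
})

test_that("VIF matches the closed form and flags rank deficiency", {
  set.seed(61)
  # exactly orthogonal, zero-mean covariates (orthogonal polynomials)
  X <- stats::poly(1:100, 3)
  colnames(X) <- c("p1", "p2", "p3")
  v <- vif(X)
  expect_true(all(abs(v$vif - 1) < 1e-8))
  # correlation r: VIF = 1/(1 - r^2)
  n <- 100000
  a <- rnorm(n); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  v2 <- vif(cbind(a = a, b = b))
  expect_equal(v2$vif, rep(1 / (1 - cor(a, b)^2), 2), tolerance = 1e-8)
  expect_lt(abs(v2$vif[1] - 1 / (1 - 0.81)), 0.25)
  # against the brute-force lm oracle on a random design
  Xr <- matrix(rnorm(500), 100, 5) %*% matrix(runif(25, -1, 1), 5, 5)
  colnames(Xr) <- paste0("v", 1:5)
  expect_equal(vif(Xr)$vif, unname(oracle_vif(Xr)), tolerance = 1e-8)
  # duplicated covariate: flagged severe/infinite
  v3 <- vif(cbind(a = a[1:50], b = a[1:50]))
  expect_true(all(v3$severe))
})
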