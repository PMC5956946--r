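# Brute-force reference implementations used as independent oracles.
# These deliberately enumerate all pairs / terms; they are never called by
# the package code itself.

oracle_c_binary <- function(p, y) {
  y <- as.logical(y)
  num <- 0; den <- 0
  for (i in which(y)) for (j in which(!y)) {
    den <- den + 1
    num <- num + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
  }
  num / den
}

oracle_c_survival <- function(time, event, risk, horizon) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (!event[i] || time[i] > horizon) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  if (den == 0) stop("no usable pairs")
  num / den
}

oracle_slope <- function(p, y) {
  mean(p[as.logical(y)]) - mean(p[!as.logical(y)])
}

oracle_nri <- function(p_old, p_new, y) {
  y <- as.logical(y)
  up <- p_new > p_old; down <- p_new < p_old
  ev <- mean(up[y]) - mean(down[y])
  ne <- mean(down[!y]) - mean(up[!y])
  c(overall = ev + ne, event = ev, nonevent = ne)
}

oracle_vif <- function(X) {
  X <- as.matrix(X)
  sapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  })
}

# Efron-tie Cox partial log-likelihood evaluated directly from the formula
oracle_efron_loglik <- function(time, event, X, beta) {
  eta <- drop(as.matrix(X) %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event]))) {
    D <- which(event & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumR <- sum(w[R]); sumD <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

# small synthetic survival dataset with proportional hazards
sim_ph_data <- function(n, beta, censor_rate = 0, shape = 1, scale = 10,
                        x = NULL) {
  if (is.null(x)) x <- stats::rnorm(n)
  u <- stats::runif(n)
  t_ev <- scale * (-log(u) / exp(beta * x))^(1 / shape)
  cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  data.frame(x = x, time = pmin(t_ev, cens), event = t_ev <= cens)
}

expect_equal10 <- function(a, b) expect_equal(a, b, tolerance = 1e-10)
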