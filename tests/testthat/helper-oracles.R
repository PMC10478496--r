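# Independent oracles: closed-form / brute-force routes kept deliberately
# separate from the package implementation.

# least squares by explicit normal equations
ols_oracle <- function(y, X) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- unname(sqrt(diag(XtX_inv) * s2))
  tval <- as.vector(beta) / se
  list(beta = as.vector(beta), se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df,
       r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# logistic regression by explicit Newton-Raphson on the log-likelihood
logistic_newton_oracle <- function(y, X, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- t(X) %*% (y - p)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  se <- unname(sqrt(diag(solve(t(X) %*% (X * (p * (1 - p)))))))
  list(beta = beta, se = se, z = beta / se)
}

# dense-grid quadrature posterior for a single-group ZOIB model with gamma
# fixed at zero; exploits that the likelihood separates into an alpha part
# and a (mu, phi) part, so the posterior factorises over independent grids
grid_zoib_posterior <- function(y, sd_a = sqrt(1000), sd_m = sqrt(1000),
                                sd_f = sqrt(100), n1d = 4001, n2d = 241) {
  n0 <- sum(y == 0)
  mid <- y[y > 0 & y < 1]
  nm <- length(mid)
  sly <- sum(log(mid)); sl1y <- sum(log1p(-mid))
  # alpha part on a 1-D grid of logit(alpha)
  ahat <- (n0 + 0.5) / (length(y) + 1)
  a0 <- stats::qlogis(ahat)
  ag <- seq(a0 - 3, a0 + 3, length.out = n1d)
  lpa <- n0 * log(stats::plogis(ag)) + nm * log1p(-stats::plogis(ag)) +
    stats::dnorm(ag, 0, sd_a, log = TRUE)
  wa <- exp(lpa - max(lpa)); wa <- wa / sum(wa)
  # (mu, phi) part on a 2-D grid of (logit(mu), log(phi))
  m0 <- stats::qlogis(mean(mid))
  mg <- seq(m0 - 1.5, m0 + 1.5, length.out = n2d)
  fg <- seq(log(1), log(200), length.out = n2d)
  mu <- stats::plogis(mg)
  ll_mf <- outer(seq_along(mg), seq_along(fg), function(i, j) {
    m <- mu[i]; phi <- exp(fg[j])
    nm * (lgamma(phi) - lgamma(m * phi) - lgamma((1 - m) * phi)) +
      (m * phi - 1) * sly + ((1 - m) * phi - 1) * sl1y
  })
  lp_mf <- ll_mf + outer(stats::dnorm(mg, 0, sd_m, log = TRUE),
                         stats::dnorm(fg, 0, sd_f, log = TRUE), `+`)
  w_mf <- exp(lp_mf - max(lp_mf)); w_mf <- w_mf / sum(w_mf)
  # deviance = -2 (loglik_a + loglik_mf); expectation separates
  lla <- n0 * log(stats::plogis(ag)) + nm * log1p(-stats::plogis(ag))
  e_lla <- sum(wa * lla)
  e_llmf <- sum(w_mf * ll_mf)
  d_bar <- -2 * (e_lla + e_llmf)
  a_bar <- sum(wa * ag)
  m_bar <- sum(rowSums(w_mf) * mg)
  f_bar <- sum(colSums(w_mf) * fg)
  mu_b <- stats::plogis(m_bar); phi_b <- exp(f_bar)
  d_hat <- -2 * (n0 * log(stats::plogis(a_bar)) + nm * log1p(-stats::plogis(a_bar)) +
                   nm * (lgamma(phi_b) - lgamma(mu_b * phi_b) - lgamma((1 - mu_b) * phi_b)) +
                   (mu_b * phi_b - 1) * sly + ((1 - mu_b) * phi_b - 1) * sl1y)
  list(mean_alpha = sum(wa * stats::plogis(ag)),
       mean_mu = sum(rowSums(w_mf) * stats::plogis(mg)),
       d_bar = d_bar, dic = 2 * d_bar - d_hat)
}

# wrap a bare vector of proportions into the observation schema
obs_from_values <- function(y, kind = "random", sex = NA_character_,
                            parity = NA_character_, category = "grass") {
  out <- data.frame(site_id = paste0("s", seq_along(y)),
                    group_kind = rep_len(kind, length(y)),
                    sex = rep_len(sex, length(y)),
                    parity = rep_len(parity, length(y)),
                    stringsAsFactors = FALSE)
  for (cc in habitat_categories()) out[[cc]] <- NA_real_
  out[[category]] <- y
  out
}

quick_cfg <- function(seed, chains = 3, iterations = 2500, burn_in = 600) {
  mcmc_config(chains = chains, iterations = iterations, burn_in = burn_in,
              seed = seed)
}
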