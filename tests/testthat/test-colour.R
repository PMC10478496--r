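test_that("RGB to HSL reproduces reference colours", {
  red <- rgb_to_hsl(255, 0, 0)
  expect_equal(c(red$h, red$s, red$l), c(0, 100, 50))
  white <- rgb_to_hsl(255, 255, 255)
  expect_equal(white$s, 0)
  expect_equal(white$l, 100)
  expect_true(white$grey)
  olive <- rgb_to_hsl(128, 128, 0)
  expect_equal(olive$h, 60)
  expect_equal(olive$s, 100)
  expect_equal(olive$l, 50 * 128 / 255, tolerance = 1e-12)  # ~25.1
  expect_error(rgb_to_hsl(300, 0, 0), "\\[0, 255\\]")
})

test_that("HSL round trip is faithful within one channel step", {
  set.seed(61)
  rgb <- matrix(sample(0:255, 3 * 300, replace = TRUE), ncol = 3)
  hsl <- rgb_to_hsl(rgb[, 1], rgb[, 2], rgb[, 3])
  back <- hsl_to_rgb(hsl$h, hsl$s, hsl$l)
  expect_true(all(abs(back$r - rgb[, 1]) <= 1 / 255 + 1e-9))
  expect_true(all(abs(back$g - rgb[, 2]) <= 1 / 255 + 1e-9))
  expect_true(all(abs(back$b - rgb[, 3]) <= 1 / 255 + 1e-9))
})

test_that("least squares agrees with the normal-equations oracle", {
  # a fixed printed dataset of 10 (x, y) pairs
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3, 7.7, 8.1, 9.4, 10.0)
  y <- c(2.9, 4.1, 6.2, 8.8, 9.1, 12.0, 14.6, 15.1, 18.2, 19.3)
  X <- cbind(intercept = 1, x = x)
  fit <- fit_ols(y, X)
  oracle <- ols_oracle(y, X)
  expect_equal(fit$coefficients$estimate, oracle$beta, tolerance = 1e-10)
  expect_equal(fit$coefficients$se, oracle$se, tolerance = 1e-10)
  expect_equal(fit$coefficients$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-12)
  expect_equal(fit$df_residual, 8)

  # permutation invariance
  perm <- sample(10)
  fit2 <- fit_ols(y[perm], X[perm, ])
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate)

  # exact linear response ("perfect fit" warning from the summary is expected)
  fit3 <- suppressWarnings(fit_ols(3 + 2 * x, X))
  expect_equal(fit3$r_squared, 1)

  # collinearity is reported by column name
  expect_error(fit_ols(y, cbind(intercept = 1, x = x, x2 = 2 * x)),
               "collinear column.*x2")
})

test_that("one-way ANOVA matches its algebraic identities", {
  # equal group means: zero between-group variance
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- one_way_anova(v, g)
  expect_equal(res$f_value, 0)

  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(17)
  v <- c(rnorm(12, 0), rnorm(15, 0.8))
  g <- rep(c("a", "b"), c(12, 15))
  res <- one_way_anova(v, g)
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$f_value, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)

  # three groups over 302 values: df (2, 299)
  set.seed(18)
  v <- rnorm(302)
  g <- sample(c("reticulated", "intermediate", "linear"), 302, replace = TRUE,
              prob = c(0.4, 0.2, 0.4))
  # force exact sizes irrelevant; only total n matters for df_within
  res <- one_way_anova(v, g)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 299)

  expect_error(one_way_anova(1:5, rep("a", 5)), "two groups")
})

test_that("logistic regression agrees with a Newton-Raphson oracle", {
  set.seed(23)
  n <- 120
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rnorm(n))
  eta <- X %*% c(-0.3, 0.9, 0)
  y <- as.numeric(runif(n) < 1 / (1 + exp(-eta)))
  fit <- fit_logistic(y, X)
  oracle <- logistic_newton_oracle(y, X)
  expect_equal(fit$coefficients$estimate, oracle$beta, tolerance = 1e-6)
  expect_equal(fit$coefficients$se, oracle$se, tolerance = 1e-6)
  # a predictor unrelated to the response has a small z statistic
  expect_lt(abs(fit$coefficients$statistic[fit$coefficients$term == "x2"]), 2)
  # flipping labels negates every coefficient
  fit_flip <- fit_logistic(1 - y, X)
  expect_equal(fit_flip$coefficients$estimate, -fit$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("complete separation is flagged", {
  x <- c(-2, -1.5, -1, 1, 1.5, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fit_logistic(y, cbind(intercept = 1, x = x)),
                 "separation")
  expect_true(fit$separation)
})

test_that("the colour model suite recovers generative structure", {
  records <- generate_colour_dataset(colour_scenario(n = 400, seed = 55))
  models <- run_colour_models(records)
  # dorsal hue ~ habitat hue: slope near the generating 0.21
  m6 <- models$model6$h_no_sex
  slope <- m6$coefficients[m6$coefficients$term == "habitat_h", ]
  expect_lt(abs(slope$estimate - 0.21), 2 * slope$se)
  # basking ~ habitat slope near the generating 0.39
  m4 <- models$model4$h
  s4 <- m4$coefficients[m4$coefficients$term == "habitat_h", ]
  expect_lt(abs(s4$estimate - 0.39), 2 * s4$se)
  # all eight models are reported with raw p-values only
  expect_setequal(names(models), paste0("model", 1:8))
  expect_true("p_value" %in% names(m4$coefficients))
  expect_false(any(grepl("adjust", unlist(lapply(models, names)))))
})

test_that("identical basking and habitat colour gives a perfect model 4 fit", {
  records <- generate_colour_dataset(colour_scenario(n = 80, seed = 7))
  records$basking_h <- records$habitat_h
  records$basking_s <- records$habitat_s
  records$basking_l <- records$habitat_l
  models <- suppressWarnings(run_colour_models(records))  # perfect-fit warnings
  for (ch in c("h", "s", "l")) {
    fit <- models$model4[[ch]]
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_equal(fit$coefficients$estimate[2], 1, tolerance = 1e-10)
  }
})

test_that("no sex effect on pattern keeps the model 2 z statistic small", {
  flagged <- 0
  for (r in 1:20) {
    records <- generate_colour_dataset(
      colour_scenario(n = 165, pattern_sex_logodds = 0, seed = 500 + r))
    m2 <- run_colour_models(records)$model2
    z <- m2$coefficients$statistic[m2$coefficients$term == "sex_male"]
    flagged <- flagged + (abs(z) >= 2)
  }
  expect_lte(flagged, 2)  # nominal type-I behaviour in >= 90% of runs
})

test_that("admixed individuals are excluded and missing rows are counted", {
  records <- generate_colour_dataset(colour_scenario(n = 60, seed = 9))
  records$parity[1:10] <- "admixed"
  records$habitat_h[11:15] <- NA
  models <- run_colour_models(records)
  m6 <- models$model6$h_no_sex
  expect_equal(m6$n_used, 45)
  expect_equal(m6$n_dropped, 5)
})

test_that("hue near the circular wrap triggers the linearity warning", {
  records <- generate_colour_dataset(colour_scenario(n = 40, seed = 3))
  records$dorsal_h[1] <- 355
  expect_warning(run_colour_models(records), "wrap")
})

test_that("both pattern codings are supported", {
  records <- generate_colour_dataset(colour_scenario(n = 200, seed = 77))
  m_rest <- run_colour_models(records, pattern_coding = "reticulated_vs_rest")$model2
  m_lin <- run_colour_models(records, pattern_coding = "reticulated_vs_linear")$model2
  # dropping intermediates reduces the usable sample
  expect_lt(m_lin$n_used, m_rest$n_used)
  expect_equal(m_rest$n_used, 200)
})
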