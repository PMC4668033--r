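test_that("OLS recovers generating parameters from noise-free data", {
  truth <- mm3()$params
  vc0 <- taper_varcomp("a1", matrix(0), matrix(0), sigma2 = 1e-12)
  d <- simulate_taper_data(n_plots = 6, trees_per_plot = 3, seed = 2,
                           params = truth, varcomp = vc0,
                           round_measurements = FALSE)
  fit <- taper_fit(d, method = "OLS")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-5)
  expect_lt(fit$sigma2, 1e-10)
})

test_that("OLS agrees with an independent Levenberg-Marquardt fit", {
  skip_if_not_installed("minpack.lm")
  d <- small_data()
  fit <- small_ols()
  df <- as.data.frame(d)
  form <- d_i ~ a0 * d^a1 * h^a2 *
    (((1 - (h_i / h)^(1/3)) / (1 - (1.3 / h)^(1/3)))^
       (b1 * (h_i / h)^4 + b2 * exp(-d / h) +
          b3 * ((1 - (h_i / h)^(1/3)) / (1 - (1.3 / h)^(1/3)))^0.1 +
          b4 / d + b5 * h^(1 - (h_i / h)^(1/3)) +
          b6 * (1 - (h_i / h)^(1/3)) / (1 - (1.3 / h)^(1/3))))
  lm_fit <- minpack.lm::nlsLM(form, data = df,
                              start = as.list(coef(fit)),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(sum(residuals(lm_fit)^2), sum(residuals(fit)^2),
               tolerance = 1e-6)
  expect_equal(unname(coef(lm_fit)), unname(coef(fit)), tolerance = 1e-3)
})

test_that("OLS errors on underdetermined data", {
  one <- taper_data(data.frame(plot = 1, tree = 1, d = 24, h = 14,
                               h_i = c(1, 2, 4, 6), d_i = c(23, 21, 18, 15)))
  expect_error(taper_fit(one, method = "OLS"), "underdetermined")
})

test_that("GLS nests OLS and improves the likelihood", {
  d <- small_data()
  ols <- small_ols()
  gls_null <- taper_fit(d, method = "GLS", variance = FALSE, car1 = FALSE)
  expect_equal(unname(coef(gls_null)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(gls_null$loglik, ols$loglik, tolerance = 1e-8)

  gls <- taper_fit(d, method = "GLS", variance = TRUE, car1 = FALSE)
  expect_gte(gls$loglik, ols$loglik)
  gls_full <- taper_fit(d, method = "GLS", variance = TRUE, car1 = TRUE)
  expect_gte(gls_full$loglik + 1e-6, gls$loglik)
})

test_that("GLS recovers the variance-power and CAR(1) parameters", {
  # fixed-effects data with heteroscedastic, serially correlated errors
  vc <- taper_varcomp("a1", matrix(0), matrix(0), sigma2 = 0.01,
                      delta = 0.7, phi = 0.5)
  deltas <- phis <- numeric(4)
  for (r in 1:4) {
    d <- simulate_taper_data(n_plots = 15, trees_per_plot = 4, seed = 100 + r,
                             varcomp = vc, round_measurements = FALSE)
    g <- taper_fit(d, method = "GLS", variance = TRUE, car1 = TRUE)
    deltas[r] <- g$delta; phis[r] <- g$phi
  }
  expect_lt(abs(mean(deltas) - 0.7), 3 * sd(deltas) / 2 + 0.05)
  expect_lt(abs(mean(phis) - 0.5), 3 * sd(phis) / 2 + 0.05)
})

test_that("FOCE matches the nlme oracle on a single-random-parameter model", {
  skip_if_not_installed("nlme")
  vcfull <- mm3()$varcomp
  vc1 <- taper_varcomp("b3", vcfull$D_plot["b3", "b3", drop = FALSE],
                       vcfull$D_tree["b3", "b3", drop = FALSE],
                       sigma2 = 0.68)
  d <- simulate_taper_data(n_plots = 15, trees_per_plot = 4, seed = 11,
                           varcomp = vc1, round_measurements = FALSE)
  mine <- taper_fit(d, method = "FOCE", random = "b3", criterion = "REML",
                    variance = FALSE)
  df <- as.data.frame(d)
  df$tree_f <- factor(paste(df$plot, df$tree, sep = "::"))
  df$plot_f <- factor(df$plot)
  form <- d_i ~ a0 * d^a1 * h^a2 *
    (((1 - (h_i / h)^(1/3)) / (1 - (1.3 / h)^(1/3)))^
       (b1 * (h_i / h)^4 + b2 * exp(-d / h) +
          b3 * ((1 - (h_i / h)^(1/3)) / (1 - (1.3 / h)^(1/3)))^0.1 +
          b4 / d + b5 * h^(1 - (h_i / h)^(1/3)) +
          b6 * (1 - (h_i / h)^(1/3)) / (1 - (1.3 / h)^(1/3))))
  oracle <- nlme::nlme(form, data = df,
                       fixed = a0 + a1 + a2 + b1 + b2 + b3 + b4 + b5 + b6 ~ 1,
                       random = b3 ~ 1 | plot_f / tree_f,
                       start = coef(taper_fit(d, method = "OLS")),
                       method = "REML",
                       control = nlme::nlmeControl(maxIter = 200, msMaxIter = 200,
                                                   tolerance = 5e-4))
  expect_equal(mine$loglik, as.numeric(stats::logLik(oracle)), tolerance = 1e-4)
  expect_equal(mine$varcomp$sigma2, oracle$sigma^2, tolerance = 0.02)
  expect_equal(unname(mine$varcomp$D_tree[1, 1]),
               as.numeric(nlme::VarCorr(oracle)[4, 1]), tolerance = 0.05)
  # the fitted population curves agree to well below measurement resolution
  f_mine <- kozak_taper(df$d, df$h, df$h_i, mine$params)
  f_oracle <- fitted(oracle, level = 0)
  expect_lt(mean(abs(f_mine - f_oracle)), 0.02)
  # tree-level EBLUPs agree
  rn <- nlme::ranef(oracle, level = 2)
  key <- sub(".*/", "", rownames(rn))
  expect_gt(cor(rn[[1]], mine$eblups$tree[key, 1]), 0.999)
})

test_that("FOCE with negligible random variation collapses to the GLS fit", {
  vc0 <- taper_varcomp("a1", matrix(1e-12), matrix(1e-12), sigma2 = 0.01,
                       delta = 0.7)
  d <- simulate_taper_data(n_plots = 10, trees_per_plot = 3, seed = 21,
                           varcomp = vc0, round_measurements = FALSE)
  gls <- taper_fit(d, method = "GLS", variance = TRUE)
  foce <- taper_fit(d, method = "FOCE", random = c("a1", "b3"),
                    criterion = "ML", variance = TRUE)
  f_gls <- kozak_taper(d$d, d$h, d$h_i, gls$params)
  f_foce <- kozak_taper(d$d, d$h, d$h_i, foce$params)
  expect_lt(mean(abs(f_gls - f_foce)), 0.01)
  expect_lt(max(abs(foce$eblups$plot)), 0.05)
})

test_that("information criteria satisfy their defining identities", {
  for (fit in list(small_ols(), small_foce())) {
    expect_identical(fit$aic, -2 * fit$loglik + 2 * fit$df)
    expect_identical(fit$bic, -2 * fit$loglik + log(fit$n_obs) * fit$df)
    expect_equal(AIC(fit), fit$aic)
    expect_equal(BIC(fit), fit$bic)
  }
})

test_that("EBLUPs are centred near zero across subjects", {
  fit <- small_foce()
  scale_p <- sqrt(diag(fit$varcomp$D_plot))
  scale_t <- sqrt(diag(fit$varcomp$D_tree))
  expect_lt(max(abs(colMeans(fit$eblups$plot)) / scale_p), 0.75)
  expect_lt(max(abs(colMeans(fit$eblups$tree)) / scale_t), 0.75)
})

test_that("model comparison table and LRT behave as declared", {
  fit <- small_foce()
  tab <- anova(fit, fit)
  expect_equal(tab$L.Ratio[2], 0, tolerance = 1e-10)
  expect_equal(tab$`p-value`[2], 1)

  ml1 <- taper_fit(small_data(), method = "GLS", variance = FALSE)
  ml2 <- taper_fit(small_data(), method = "GLS", variance = TRUE)
  tab2 <- anova(ml1, ml2)
  expect_equal(tab2$df[2] - tab2$df[1], 1)
  expect_true(tab2$`p-value`[2] < 0.05)  # heteroscedasticity is real here

  # REML fits with different fixed structures refuse the LRT
  r1 <- small_foce()
  r2 <- taper_fit(small_data(), method = "FOCE", random = c("a1", "b3"),
                  criterion = "REML", variance = TRUE,
                  active = setdiff(pinetaper:::.kozak_names, "b5"),
                  start = r1$params)
  expect_error(anova(r1, r2), "REML")
})

test_that("significance screening drops weak coefficients and refits", {
  fit <- small_foce()
  # with an absurd threshold everything non-essential is dropped
  pruned <- prune_insignificant(fit, z = 1e6)
  expect_true(length(pruned$active) < length(fit$active))
  expect_true(all(c("a0", "a1", "b3") %in% pruned$active))
  # inactive coefficients are exactly zero
  expect_true(all(pruned$params[setdiff(pinetaper:::.kozak_names,
                                        pruned$active)] == 0))
  # a fully significant fit is returned unchanged
  expect_identical(prune_insignificant(fit, z = 1e-9), fit)
})
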