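test_that("zero variance components give zero effects in one pass", {
  fit <- small_foce()
  fit0 <- fit
  fit0$varcomp <- taper_varcomp(fit$random,
                                matrix(0, 2, 2), matrix(0, 2, 2),
                                sigma2 = fit$varcomp$sigma2,
                                delta = fit$varcomp$delta)
  obs <- taper_data(data.frame(plot = "NEW", tree = "A", d = 24, h = 14,
                               h_i = 7, d_i = 12))
  cal <- calibrate(fit0, obs)
  expect_true(cal$converged)
  expect_identical(cal$iterations, 1L)
  expect_equal(unname(cal$plot_effects), c(0, 0))
  expect_equal(unname(cal$tree_effects[1, ]), c(0, 0))
})

test_that("single-observation linear-effect calibration matches the scalar
           closed form in one step", {
  # expand a0: the prediction is linear in its random effect, so the
  # iterative solver must land on the closed-form BLUP immediately
  base <- small_foce()
  fit <- base
  fit$params <- mm3()$params
  s2p <- 4e-4; s2t <- 1.6e-3; s2 <- 0.36
  fit$varcomp <- taper_varcomp("a0", matrix(s2p), matrix(s2t), sigma2 = s2)
  fit$random <- "a0"

  d <- 24; h <- 14; h_i <- 6
  obs_val <- kozak_taper(d, h, h_i, fit$params) + 1.1
  obs <- taper_data(data.frame(plot = "NEW", tree = "A", d = d, h = h,
                               h_i = h_i, d_i = obs_val))
  cal <- calibrate(fit, obs)
  z <- kozak_taper(d, h, h_i, fit$params) / fit$params["a0"]
  den <- z^2 * (s2p + s2t) + s2            # homoscedastic: g = 1
  expect_equal(unname(cal$plot_effects), unname(s2p * z * 1.1 / den),
               tolerance = 1e-8)
  expect_equal(unname(cal$tree_effects[1, 1]), unname(s2t * z * 1.1 / den),
               tolerance = 1e-8)
  expect_lte(cal$iterations, 2L)
})

test_that("an observation on the mean curve leaves the effects at zero", {
  fit <- small_foce()
  obs <- taper_data(data.frame(plot = "NEW", tree = "A", d = 24, h = 14,
                               h_i = 7, d_i = kozak_taper(24, 14, 7, fit$params)))
  cal <- calibrate(fit, obs)
  expect_lt(max(abs(c(cal$plot_effects, cal$tree_effects))), 1e-6)
})

test_that("calibration fixed point matches the penalized-criterion optimum", {
  fit <- small_foce()
  vc <- fit$varcomp
  set.seed(14)
  df <- taper_data(data.frame(
    plot = "NEW", tree = rep(c("A", "B"), each = 3),
    d = rep(c(22, 31), each = 3), h = rep(c(13, 19), each = 3),
    h_i = c(1.5, 5, 9, 2, 8, 14),
    d_i = c(21.1, 16.8, 9.5, 30.4, 22.0, 10.9)))
  cal <- calibrate(fit, df)
  b_hat <- c(cal$plot_effects, t(cal$tree_effects))

  ps <- pinetaper:::.plot_structure(df)[[1]]
  crit <- function(b) {
    sys <- pinetaper:::.assemble_system(fit$params, vc, ps, b)
    drop(t(sys$resid) %*% solve(sys$R, sys$resid) +
           t(b) %*% solve(sys$D + diag(1e-14, 6), b))
  }
  opt <- optim(b_hat * 0, crit, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(b_hat - opt$par)), 1e-4)
  expect_lte(crit(b_hat), opt$value + 1e-8)
})

test_that("calibrating on all fitting observations reproduces the stored EBLUPs", {
  fit <- small_foce()
  data <- fit$data
  for (pid in unique(data$plot)[1:3]) {
    sub <- taper_data(data[data$plot == pid, , drop = FALSE])
    cal <- calibrate(fit, sub)
    expect_true(cal$converged)
    expect_equal(unname(cal$plot_effects),
                 unname(fit$eblups$plot[pid, ]), tolerance = 1e-4)
    keys <- paste(pid, rownames(cal$tree_effects), sep = "::")
    expect_equal(unname(cal$tree_effects),
                 unname(fit$eblups$tree[keys, ]), tolerance = 1e-4)
  }
})

test_that("EBLUP norms shrink monotonically as D is scaled toward zero", {
  fit <- small_foce()
  obs <- taper_data(data.frame(plot = "NEW", tree = "A", d = 24, h = 14,
                               h_i = c(4, 7), d_i = c(17.5, 13.0)))
  norms <- vapply(c(1, 0.3, 0.1, 0.01), function(s) {
    f <- fit
    f$varcomp <- taper_varcomp(fit$random, s * fit$varcomp$D_plot,
                               s * fit$varcomp$D_tree,
                               sigma2 = fit$varcomp$sigma2,
                               delta = fit$varcomp$delta)
    cal <- calibrate(f, obs)
    sqrt(sum(c(cal$plot_effects, cal$tree_effects)^2))
  }, 1)
  expect_true(all(diff(norms) < 0))
})

test_that("subject-specific predictions compose effects correctly", {
  fit <- small_foce()
  obs <- taper_data(data.frame(plot = "NEW", tree = "A", d = 24, h = 14,
                               h_i = 7, d_i = 11))
  cal <- calibrate(fit, obs)
  grid <- c(2, 7, 11)
  manual_tree <- kozak_taper(24, 14, grid, fit$params,
                             effects = cal$plot_effects + cal$tree_effects[1, ])
  expect_equal(predict(cal, tree = "A", h_i = grid), manual_tree)
  manual_plot <- kozak_taper(24, 14, grid, fit$params,
                             effects = cal$plot_effects)
  expect_equal(predict(cal, tree = "A", h_i = grid, level = "plot"),
               manual_plot)
  expect_error(predict(cal, tree = "ZZ", h_i = grid), "unknown tree")
  # the SS curve is pulled toward the calibration observation
  m7 <- kozak_taper(24, 14, 7, fit$params)
  expect_lt(abs(predict(cal, tree = "A", h_i = 7) - 11), abs(m7 - 11))
})

test_that("a noise-free mean-response tree sweeps to zero error everywhere", {
  fit <- small_foce()
  h_i <- c(0.5, 2, 4, 6, 8, 10, 12)
  tree <- taper_data(data.frame(plot = "E", tree = "T", d = 24, h = 14,
                                h_i = h_i,
                                d_i = kozak_taper(24, 14, h_i, fit$params)))
  # volume bookkeeping differs (frustums vs quadrature), so judge diameters
  sw <- calibration_sweep(fit, tree)
  di <- sw$by_class[sw$by_class$variable == "d_i" & sw$by_class$n > 0, ]
  expect_true(all(di$rmse < 1e-5))
  vcls <- sw$by_class[sw$by_class$variable == "v" & sw$by_class$n > 0, ]
  expect_true(all(abs(vcls$mpe_pct) < 1))   # frustum-vs-quadrature gap only
  # empty classes are reported as missing, not zero
  empty <- sw$by_class[sw$by_class$n == 0, ]
  expect_true(all(is.na(empty$rmse)))
})

test_that("disaggregation recovers the pooled statistic for a single group", {
  fit <- small_foce()
  ev <- simulate_taper_data(n_plots = 2, trees_per_plot = 2, seed = 33)
  sw <- calibration_sweep(fit, ev)
  pooled <- disaggregate(sw, by = "calibration", breaks = c(0, 1))
  rec <- sw$records[sw$records$variable == "d_i", ]
  expect_equal(pooled$rmse[1], taper_rmse(rec$obs, rec$pred_ss, p = sw$p),
               tolerance = 1e-12)
  expect_identical(pooled$n[1], nrow(rec))

  # group-wise bookkeeping identity: sum rmse_g^2 (n_g - p_g) = rmse^2 (n - p)
  byc <- disaggregate(sw, by = "calibration")
  byc <- byc[byc$n > 0, ]
  p_g <- sw$p * byc$n / nrow(rec)
  expect_equal(sum(byc$rmse^2 * (byc$n - p_g)),
               pooled$rmse[1]^2 * (nrow(rec) - sw$p), tolerance = 1e-10)
})
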