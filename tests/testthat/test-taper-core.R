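test_that("relative height terms hit their anchor points", {
  t1 <- kozak_terms(1.3, 14)
  expect_equal(t1$x, 1, tolerance = 1e-12)
  t2 <- kozak_terms(14, 14)
  expect_equal(t2$q, 1)
  expect_equal(t2$w, 0)
  expect_equal(t2$x, 0)
  t3 <- kozak_terms(0, 14)
  expect_equal(t3$w, 1)
  expect_equal(t3$x, 1 / (1 - (1.3 / 14)^(1/3)), tolerance = 1e-12)
  expect_equal(t3$x, 1.827597, tolerance = 1e-6)
  expect_error(kozak_terms(0.5, 1.2), "exceed")
})

test_that("diameter prediction matches the closed form at breast height", {
  p <- mm3()$params
  # x = 1 at breast height, so the exponent term drops out entirely
  expect_equal(kozak_taper(24, 14, 1.3, p),
               1.050 * 24^0.9427 * 14^0.04734, tolerance = 1e-12)
  expect_equal(kozak_taper(24, 14, 1.3, p), 23.79974, tolerance = 1e-6)
  # tip convention
  expect_identical(kozak_taper(24, 14, 14, p), 0)
})

test_that("zero effects and absent effects agree; effects shift coefficients", {
  p <- mm3()$params
  set.seed(5)
  for (k in 1:20) {
    d <- runif(1, 8, 50); h <- runif(1, 5, 28); h_i <- runif(1, 0, h)
    expect_identical(kozak_taper(d, h, h_i, p),
                     kozak_taper(d, h, h_i, p, effects = c(a1 = 0, b3 = 0)))
  }
  shifted <- p; shifted["a1"] <- p["a1"] + 0.01
  expect_equal(kozak_taper(24, 14, 5, p, effects = c(a1 = 0.01)),
               kozak_taper(24, 14, 5, shifted), tolerance = 1e-12)
})

test_that("prediction is continuous in section height", {
  p <- mm3()$params
  grid <- seq(0, 14, length.out = 4001)
  di <- kozak_taper(24, 14, grid, p)
  expect_true(all(is.finite(di)))
  # steepest slope sits at the butt flare; jumps stay bounded by slope * step
  expect_lt(max(abs(diff(di))), 1000 * diff(grid)[1])
  # refining the grid shrinks the largest jump (no genuine discontinuity);
  # the cube-root butt profile makes the first-step jump scale as step^(1/3)
  grid2 <- seq(0, 14, length.out = 8001)
  di2 <- kozak_taper(24, 14, grid2, p)
  ratio <- max(abs(diff(di))) / max(abs(diff(di2)))
  expect_gt(ratio, 1.15); expect_lt(ratio, 2.6)
})

test_that("finite-difference gradient matches analytic derivatives", {
  p <- mm3()$params
  set.seed(11)
  for (k in 1:10) {
    d <- runif(1, 10, 45); h <- runif(1, 6, 25); h_i <- runif(1, 0.2, 0.9 * h)
    di <- kozak_taper(d, h, h_i, p)
    g <- kozak_gradient(d, h, h_i, p, wrt = c("a0", "a1", "a2", "b6"))
    x <- kozak_terms(h_i, h)$x
    expect_equal(g[, "a0"], di / p["a0"], tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(g[, "a1"], di * log(d), tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(g[, "a2"], di * log(h), tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(g[, "b6"], di * log(x) * x, tolerance = 1e-5, ignore_attr = TRUE)
  }
  # at the tip the function is identically zero
  expect_equal(unname(kozak_gradient(24, 14, 14, p)[1, ]), rep(0, 9))
  expect_error(kozak_gradient(24, 14, 5, p, wrt = "c9"), "differentiate")
})

test_that("stem volume matches a brute-force Riemann oracle and is additive", {
  p <- mm3()$params
  # cylinder limit: constant-diameter degenerate coefficients
  cyl <- kozak_params(a0 = 20, a1 = 0, a2 = 0)
  expect_equal(stem_volume(cyl, 24, 14, 0, 14), pi * (20 / 200)^2 * 14,
               tolerance = 1e-8)

  # 1e6-panel midpoint Riemann sum as independent oracle
  n <- 1e6
  mid <- (seq_len(n) - 0.5) * 14 / n
  riemann <- sum(pi * (kozak_taper(24, 14, mid, p) / 200)^2) * 14 / n
  expect_equal(stem_volume(p, 24, 14, 0, 14), riemann, tolerance = 1e-6)

  set.seed(3)
  for (cut in runif(3, 1, 13)) {
    expect_equal(stem_volume(p, 24, 14, 0, cut) + stem_volume(p, 24, 14, cut, 14),
                 stem_volume(p, 24, 14, 0, 14), tolerance = 2e-8)
  }
  expect_error(stem_volume(p, 24, 14, -1, 14), "bounds")

  # monotone in upper bound and in a0
  v1 <- stem_volume(p, 24, 14, 0, 7); v2 <- stem_volume(p, 24, 14, 0, 10)
  expect_lt(v1, v2)
  p_up <- p; p_up["a0"] <- p["a0"] * 1.1
  expect_lt(stem_volume(p, 24, 14, 0, 14), stem_volume(p_up, 24, 14, 0, 14))
})

test_that("merchantable height inverts the taper prediction", {
  p <- mm3()$params
  top <- kozak_taper(24, 14, 7, p)
  expect_equal(merchantable_height(p, 24, 14, top), 7, tolerance = 1e-4)
  expect_equal(kozak_taper(24, 14, merchantable_height(p, 24, 14, 5), p), 5,
               tolerance = 1e-6)
  # tiny top diameter -> near the tip
  expect_gt(merchantable_height(p, 24, 14, 0.01), 13.9)
  # unattainable top diameter -> sentinel
  expect_true(is.na(merchantable_height(p, 24, 14, 200)))
})

test_that("coefficient sets round-trip through the flat key-value format", {
  cs <- mm3()
  path <- withr::local_tempfile(fileext = ".json")
  write_taper_coefs(cs, path)
  back <- read_taper_coefs(path)
  expect_equal(back$params, cs$params)
  expect_equal(back$varcomp$D_plot, cs$varcomp$D_plot)
  expect_equal(back$varcomp$D_tree, cs$varcomp$D_tree)
  expect_equal(back$varcomp$sigma2, cs$varcomp$sigma2)
  expect_equal(back$varcomp$delta, cs$varcomp$delta)
  expect_identical(back$random, c("a1", "b3"))

  fm <- taper_coefs("fmols")
  expect_equal(fm$params[["a0"]], 0.9891)
  expect_equal(fm$sigma2, 1.555)
  expect_null(fm$varcomp)
})
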