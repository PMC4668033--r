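test_that("a one-tree file round-trips through CSV identically", {
  df <- one_tree_df()
  td <- taper_data(df, provenance = "hand-built")
  expect_s3_class(td, "taper_data")
  expect_identical(nrow(td), 6L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_taper_csv(td, path)
  back <- read_taper_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(td), tolerance = 0,
               ignore_attr = TRUE)

  # full-precision round trip on awkward numerics
  td2 <- taper_data(data.frame(plot = "p", tree = "t", d = 24.123456789,
                               h = 14.987654321, h_i = c(0.03, 1/3),
                               d_i = c(25.5, sqrt(2) * 10)))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_taper_csv(td2, path2)
  expect_equal(read_taper_csv(path2)$d_i, td2$d_i, tolerance = 1e-12)
})

test_that("constructor rejects invariant violations with row numbers", {
  df <- one_tree_df()
  df$h_i[3] <- df$h[1] + 0.5
  expect_error(taper_data(df), "exceeds total height.*row")
  df <- one_tree_df()
  df$d_i[2] <- -1
  expect_error(taper_data(df), "non-negative")
  df <- one_tree_df()
  df$h_i[2] <- df$h_i[1]
  expect_error(taper_data(df), "duplicate section height")
  expect_error(taper_data(transform(one_tree_df(), h = 1.2)), "exceed 1.3")
})

test_that("reading maps dialects and flags missing columns", {
  df <- one_tree_df()
  names(df) <- c("stand", "stem", "diam", "height", "sect_h", "sect_d")
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  dia <- taper_dialect(plot = "stand", tree = "stem", dbh = "diam",
                       htot = "height", hsec = "sect_h", dsec = "sect_d")
  td <- read_taper_csv(path, dialect = dia)
  expect_identical(nrow(td), 6L)
  expect_error(read_taper_csv(path), "not found.*dialect")
})

test_that("observed volume matches closed-form cone and frustum values", {
  cone <- taper_data(data.frame(plot = 1, tree = 1, d = 20, h = 10,
                                h_i = c(0, 10), d_i = c(20, 0)))
  expect_equal(observed_volume(cone)$v, pi * 10 / 3 * 0.1^2, tolerance = 1e-12)

  two <- taper_data(data.frame(plot = 1, tree = 1, d = 30, h = 10,
                               h_i = c(0, 5), d_i = c(30, 20)))
  frustum <- pi * 5 / 3 * (0.15^2 + 0.15 * 0.10 + 0.10^2)
  expect_equal(observed_volume(two)$v, frustum + pi * 5 / 3 * 0.10^2,
               tolerance = 1e-12)

  zero <- taper_data(data.frame(plot = 1, tree = 1, d = 20, h = 10,
                                h_i = c(0, 4, 9), d_i = c(0, 0, 0)))
  expect_equal(observed_volume(zero)$v, 0)

  single <- taper_data(data.frame(plot = 1, tree = 1, d = 20, h = 10,
                                  h_i = 1.3, d_i = 18))
  expect_error(observed_volume(single), "at least 2 sections")
})

test_that("observed volume is additive over a split of the section list", {
  set.seed(42)
  h_i <- sort(runif(9, 0, 13))
  d_i <- rev(sort(runif(9, 0, 30)))
  tr <- function(hs, ds, h) pinetaper:::.frustum_volume(hs, ds, h)
  whole <- tr(h_i, d_i, 14)
  for (cut in c(3, 5, 7)) {
    left <- sum(pi * diff(h_i[1:cut]) / 3 *
                  ((d_i[1:(cut - 1)] / 200)^2 +
                     d_i[1:(cut - 1)] * d_i[2:cut] / 200^2 +
                     (d_i[2:cut] / 200)^2))
    right <- tr(h_i[cut:9], d_i[cut:9], 14)
    expect_equal(left + right, whole, tolerance = 1e-12)
  }
})

test_that("plot split is reproducible, exhaustive and never separates a plot", {
  d <- small_data()
  sp <- split_by_plot(d, fit_fraction = 0.7, seed = 1)
  sp2 <- split_by_plot(d, fit_fraction = 0.7, seed = 1)
  expect_identical(sp$fit$plot, sp2$fit$plot)
  expect_equal(length(unique(sp$fit$plot)), round(0.7 * 12))
  expect_length(intersect(unique(sp$fit$plot), unique(sp$eval$plot)), 0)
  expect_setequal(c(unique(sp$fit$plot), unique(sp$eval$plot)), unique(d$plot))
  # trees of one plot stay together: every tree's rows all land on one side
  expect_identical(nrow(sp$fit) + nrow(sp$eval), nrow(d))

  one <- taper_data(one_tree_df())
  expect_error(split_by_plot(one, 0.5, 1), "at least 2 plots")
})
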