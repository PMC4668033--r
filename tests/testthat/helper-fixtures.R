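# Shared fixtures.  Heavy fits are memoised so several test files can reuse
# them without refitting.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# One hand-built tree: d = 24 cm, h = 14 m, six sections.
one_tree_df <- function(plot = "P1", tree = "T1") {
  data.frame(plot = plot, tree = tree, d = 24, h = 14,
             h_i = c(0.1, 1.3, 3.3, 6.3, 9.3, 12.3),
             d_i = c(27.5, 23.8, 21.9, 18.2, 12.8, 5.9),
             stringsAsFactors = FALSE)
}

# Small two-level synthetic dataset (moderate noise, MM3-style truth).
small_data <- function() {
  memo("small_data", function() simulate_taper_data(n_plots = 12, trees_per_plot = 4, seed = 7))
}

# FOCE fit of the small dataset, shared across test files.
small_foce <- function() {
  memo("small_foce", function()
    taper_fit(small_data(), method = "FOCE", random = c("a1", "b3"),
              criterion = "REML", variance = TRUE))
}

small_ols <- function() {
  memo("small_ols", function() taper_fit(small_data(), method = "OLS"))
}

mm3 <- function() taper_coefs("mm3")
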