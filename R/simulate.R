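# Hierarchical synthetic taper data with the statistical structure the
# analysis assumes, plus the parameter-recovery harness.

# Multivariate normal draws via the Cholesky factor (PSD-safe: a zero matrix
# yields zero draws).
.rmvnorm <- function(n, Sigma) {
  k <- nrow(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  A <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
  matrix(stats::rnorm(n * k), n, k) %*% A
}

#' Generate a synthetic hierarchical taper dataset
#'
#' Emulates the study design behind the packaged coefficient sets: plots of
#' several felled trees, each stem crosscut at a stump section and then at
#' unequally spaced log ends up to near the tip.  Tree DBH follows a
#' truncated lognormal spanning the observed 6.5-56.9 cm range; total height
#' follows the allometry `h = 1.3 + alpha * d^gamma` with lognormal
#' multiplicative noise.  Section diameters are the taper-equation mean (with
#' plot- and tree-level random effects on the `random` parameters) plus
#' Gaussian noise with standard deviation `sigma * d^delta` and optional
#' within-tree CAR(1) correlation; negative simulated diameters are
#' truncated at 0 and counted.
#'
#' @param n_plots,trees_per_plot design size (defaults: 70 plots of 6 trees).
#' @param params generating fixed coefficients (default: the packaged
#'   mixed-model set).
#' @param varcomp generating variance components ([taper_varcomp()]; default:
#'   the packaged mixed-model set, without CAR(1)).
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @param dbh_meanlog,dbh_sdlog,dbh_range lognormal DBH law (cm), resampled
#'   into `dbh_range`.
#' @param height_alpha,height_gamma,height_sdlog,height_range height-DBH
#'   allometry and its multiplicative noise, resampled into `height_range` (m).
#' @param stump_range uniform range of the stump-section height (m).
#' @param log_range uniform range of log lengths (m); lengths are capped at
#'   an eighth of the stem span so short trees still yield full section
#'   schedules, and schedules run to within 0.3 m of the tip.
#' @param section_range admissible per-tree section counts.
#' @param round_measurements round recorded `d_i` to 0.1 cm and `h_i` to
#'   0.01 m, like the field protocol.
#' @return a `taper_data` with attributes `effects` (list of the true
#'   plot- and tree-level effect matrices), `params`, `varcomp` and
#'   `n_truncated` (count of negative diameters clipped to 0).
#' @export
simulate_taper_data <- function(n_plots = 70L, trees_per_plot = 6L,
                                params = taper_coefs("mm3")$params,
                                varcomp = taper_coefs("mm3")$varcomp,
                                seed = 1L,
                                dbh_meanlog = 3.071, dbh_sdlog = 0.415,
                                dbh_range = c(6.5, 56.9),
                                height_alpha = 1.01, height_gamma = 0.8,
                                height_sdlog = 0.12,
                                height_range = c(3.6, 29.5),
                                stump_range = c(0.03, 0.40),
                                log_range = c(0.3, 2.5),
                                section_range = c(7L, 24L),
                                round_measurements = TRUE) {
  stopifnot(n_plots >= 1L, trees_per_plot >= 1L)
  params <- .full_params(params)
  with_seed(seed, {
    nr <- length(varcomp$random)
    bp <- .rmvnorm(n_plots, varcomp$D_plot)
    bt <- .rmvnorm(n_plots * trees_per_plot, varcomp$D_tree)
    colnames(bp) <- colnames(bt) <- varcomp$random
    plot_ids <- sprintf("P%02d", seq_len(n_plots))
    rownames(bp) <- plot_ids
    rows <- list()
    tree_keys <- character(n_plots * trees_per_plot)
    n_trunc <- 0L
    t_idx <- 0L
    for (i in seq_len(n_plots)) {
      for (j in seq_len(trees_per_plot)) {
        t_idx <- t_idx + 1L
        d <- .resample(function() stats::rlnorm(1, dbh_meanlog, dbh_sdlog),
                       function(z) z >= dbh_range[1] && z <= dbh_range[2])
        hfun <- function() 1.3 + height_alpha * d^height_gamma *
          stats::rlnorm(1, 0, height_sdlog)
        h <- .resample(hfun, function(z) z >= height_range[1] && z <= height_range[2])
        h_i <- .section_schedule(h, stump_range, log_range, section_range)
        eff <- stats::setNames(bp[i, ] + bt[t_idx, ], varcomp$random)
        mu <- kozak_taper(d, h, h_i, params, effects = eff)
        g <- if (is.null(varcomp$delta)) 1 else d^varcomp$delta
        M <- if (is.null(varcomp$phi)) diag(length(h_i))
             else car1_matrix(h_i, varcomp$phi)
        e <- sqrt(varcomp$sigma2) * g * drop(t(chol(M)) %*% stats::rnorm(length(h_i)))
        d_i <- mu + e
        n_trunc <- n_trunc + sum(d_i < 0)
        d_i <- pmax(d_i, 0)
        if (round_measurements) {
          d_i <- round(d_i, 1)
          h_i <- round(h_i, 2)
          d <- round(d, 1); h <- round(h, 2)
        }
        key <- sprintf("T%d", j)
        tree_keys[t_idx] <- paste(plot_ids[i], key, sep = "::")
        rows[[t_idx]] <- data.frame(plot = plot_ids[i], tree = key,
                                    d = d, h = h, h_i = h_i, d_i = d_i,
                                    stringsAsFactors = FALSE)
      }
    }
    rownames(bt) <- tree_keys
    out <- taper_data(do.call(rbind, rows), provenance = "synthetic")
    attr(out, "effects") <- list(plot = bp, tree = bt)
    attr(out, "params") <- params
    attr(out, "varcomp") <- varcomp
    attr(out, "n_truncated") <- n_trunc
    out
  })
}

.resample <- function(draw, ok, max_tries = 100L) {
  for (k in seq_len(max_tries)) {
    z <- draw()
    if (ok(z)) return(z)
  }
  stop("could not draw an admissible value in ", max_tries, " tries")
}

# Stump section plus log ends; log lengths are uniform, capped so that even
# short stems produce at least the minimum section count, with schedules
# stopping 0.3 m below the tip.
.section_schedule <- function(h, stump_range, log_range, section_range) {
  for (try in 1:50) {
    stump <- stats::runif(1, stump_range[1], min(stump_range[2], h / 10))
    cap <- max(log_range[1] + 0.01, min(log_range[2], (h - stump) / 8))
    h_i <- stump
    while (length(h_i) < section_range[2]) {
      nxt <- h_i[length(h_i)] + stats::runif(1, log_range[1], cap)
      if (nxt > h - 0.3) break
      h_i <- c(h_i, nxt)
    }
    if (length(h_i) >= section_range[1]) return(h_i)
  }
  stop("could not build a section schedule with at least ",
       section_range[1], " sections for h = ", h)
}

#' Parameter-recovery experiment
#'
#' Generates replicate synthetic datasets from known truth, fits each with
#' [taper_fit()], and summarizes recovery of the fixed coefficients: mean
#' bias, empirical standard error, and coverage of nominal 95\% Wald
#' intervals.  Replicates that fail to converge are reported, not dropped.
#'
#' @param n_replicates number of replicate datasets.
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @param generator named list of arguments passed to
#'   [simulate_taper_data()].
#' @param fit_args named list of arguments passed to [taper_fit()]
#'   (default: FOCE-REML with random effects in `a1` and `b3` and the
#'   power variance function).
#' @return an object of class `taper_recovery`: `summary` (per-parameter
#'   table), `estimates` (replicate x parameter matrix), `varcomp_estimates`,
#'   `failures` (indices of non-converged replicates).
#' @export
recovery_experiment <- function(n_replicates = 10L, seed = 1L,
                                generator = list(), fit_args = list()) {
  stopifnot(n_replicates >= 1L)
  fit_defaults <- list(method = "FOCE", random = c("a1", "b3"),
                       criterion = "REML", variance = TRUE, car1 = FALSE)
  fit_args <- utils::modifyList(fit_defaults, fit_args)
  gen0 <- utils::modifyList(list(), generator)
  truth_params <- .full_params(gen0$params %||% taper_coefs("mm3")$params)
  truth_vc <- gen0$varcomp %||% taper_coefs("mm3")$varcomp
  est <- list(); vc_est <- list(); failures <- integer()
  for (r in seq_len(n_replicates)) {
    data <- do.call(simulate_taper_data,
                    utils::modifyList(gen0, list(seed = seed + r)))
    fit <- tryCatch(do.call(taper_fit, c(list(data = data), fit_args)),
                    error = function(e) e)
    if (inherits(fit, "error") || !isTRUE(fit$converged)) {
      failures <- c(failures, r)
      if (inherits(fit, "error")) next
    }
    est[[length(est) + 1L]] <-
      c(fit$params[fit$active], se = fit$se[fit$active],
        replicate = r)
    if (!is.null(fit$varcomp)) {
      vc <- fit$varcomp
      vc_est[[length(vc_est) + 1L]] <- c(
        sigma2 = vc$sigma2,
        delta = if (is.null(vc$delta)) NA_real_ else vc$delta,
        D_plot = vc$D_plot[upper.tri(vc$D_plot, diag = TRUE)],
        D_tree = vc$D_tree[upper.tri(vc$D_tree, diag = TRUE)])
    }
  }
  if (!length(est)) stop("no replicate produced estimates")
  E <- do.call(rbind, est)
  params <- intersect(.kozak_names, colnames(E))
  summ <- do.call(rbind, lapply(params, function(pp) {
    v <- E[, pp]
    se_hat <- E[, paste0("se.", pp)]
    ci_lo <- v - 1.96 * se_hat; ci_hi <- v + 1.96 * se_hat
    data.frame(param = pp, truth = truth_params[pp], mean = mean(v),
               bias = mean(v) - truth_params[pp],
               emp_se = stats::sd(v),
               coverage = mean(ci_lo <= truth_params[pp] & truth_params[pp] <= ci_hi),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, estimates = E,
                 varcomp_estimates = if (length(vc_est)) do.call(rbind, vc_est),
                 truth = list(params = truth_params, varcomp = truth_vc),
                 failures = failures, n_replicates = n_replicates),
            class = "taper_recovery")
}

#' @export
print.taper_recovery <- function(x, ...) {
  cat("Parameter recovery over", x$n_replicates, "replicates")
  if (length(x$failures))
    cat(" (non-converged:", paste(x$failures, collapse = ", "), ")")
  cat("\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
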