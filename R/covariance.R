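# Variance and correlation structures, and the block system of the
# multilevel EBLUP calibration equations.

#' Power-of-DBH variance weights
#'
#' The residual standard deviation is modelled as proportional to a power of
#' DBH: `sd(e) = sigma * g` with `g = d^delta`, so the residual variance is
#' `sigma^2 * d^(2*delta)`.  `delta = 0` recovers homoscedastic errors.
#'
#' @param d DBH (cm), positive.
#' @param delta variance-power exponent.
#' @return weights `g = d^delta`.
#' @export
variance_weights <- function(d, delta) {
  if (any(d <= 0)) stop("'d' must be positive")
  d^delta
}

#' Continuous AR(1) correlation matrix
#'
#' Correlation between two sections of the same tree is `phi` raised to the
#' absolute difference of their heights in metres, which handles the
#' unequally spaced section schedule.
#'
#' @param heights section heights (m).
#' @param phi CAR(1) coefficient in `[0, 1)`.
#' @return an n x n correlation matrix (identity when `phi = 0`).
#' @export
car1_matrix <- function(heights, phi) {
  if (length(phi) != 1L || is.na(phi) || phi < 0 || phi >= 1)
    stop("'phi' must lie in [0, 1)")
  phi^abs(outer(heights, heights, "-"))
}

#' Variance components of the two-level model
#'
#' Bundles the plot- and tree-level random-effect covariance matrices with
#' the residual variance, the variance-power exponent and the CAR(1)
#' coefficient.
#'
#' @param random character vector of parameter names carrying random effects.
#' @param D_plot,D_tree symmetric positive-semidefinite covariance matrices
#'   (`length(random)` square), plot and tree level.
#' @param sigma2 residual variance scale, `> 0`.
#' @param delta variance-power exponent, or `NULL` for homoscedastic errors.
#' @param phi CAR(1) coefficient in `[0, 1)`, or `NULL` for independent
#'   within-tree errors.
#' @return an object of class `taper_varcomp`.
#' @export
taper_varcomp <- function(random, D_plot, D_tree, sigma2, delta = NULL, phi = NULL) {
  k <- length(random)
  stopifnot(k >= 1L, all(random %in% .kozak_names))
  D_plot <- .check_cov(D_plot, k, random, "D_plot")
  D_tree <- .check_cov(D_tree, k, random, "D_tree")
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("'sigma2' must be positive")
  if (!is.null(phi) && (phi < 0 || phi >= 1)) stop("'phi' must lie in [0, 1)")
  structure(list(random = random, D_plot = D_plot, D_tree = D_tree,
                 sigma2 = sigma2, delta = delta, phi = phi),
            class = "taper_varcomp")
}

.check_cov <- function(D, k, random, what) {
  D <- as.matrix(D)
  if (!all(dim(D) == k)) stop("'", what, "' must be ", k, " x ", k)
  if (max(abs(D - t(D))) > 1e-10) stop("'", what, "' must be symmetric")
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("'", what, "' must be positive semidefinite")
  dimnames(D) <- list(random, random)
  D
}

#' @export
print.taper_varcomp <- function(x, ...) {
  cat("Variance components (random effects in ",
      paste(x$random, collapse = ", "), ")\n", sep = "")
  cat("  Plot level:\n"); print(signif(x$D_plot, 4))
  cat("  Tree level:\n"); print(signif(x$D_tree, 4))
  cat(sprintf("  sigma2 = %.4g", x$sigma2))
  if (!is.null(x$delta)) cat(sprintf("; delta = %.4g (sd multiplier d^delta)", x$delta))
  if (!is.null(x$phi)) cat(sprintf("; CAR(1) phi = %.4g", x$phi))
  cat("\n")
  invisible(x)
}

# ---- log-Cholesky parameterization of a covariance matrix -------------------
# theta = (log diag of L, then lower off-diagonals column-major); D = L L'.

.theta_to_cov <- function(theta, k) {
  L <- matrix(0, k, k)
  diag(L) <- exp(theta[seq_len(k)])
  if (k > 1L) L[lower.tri(L)] <- theta[-seq_len(k)]
  tcrossprod(L)
}

.cov_to_theta <- function(D, floor = 1e-10) {
  k <- nrow(D)
  L <- t(chol(D + diag(floor, k)))
  c(log(diag(L)), L[lower.tri(L)])
}

.n_theta <- function(k) k * (k + 1L) / 2L

# ---- block system for EBLUP calibration (and FOCE linearization) ------------

# Internal core: given the per-row structure of the trees of ONE plot, the
# fixed parameters, the variance components and the current stacked effect
# vector b = (b_plot, b_tree_1, ..., b_tree_J), build D, Z, R and the raw
# residual y - f(beta, b).
.assemble_system <- function(params, varcomp, plot_rows, b) {
  nr <- length(varcomp$random)
  trees <- plot_rows$trees            # list of per-tree row structures
  J <- length(trees)
  n <- sum(vapply(trees, function(t) length(t$h_i), 1L))
  q <- nr * (1L + J)
  stopifnot(length(b) == q)

  # effects per row: plot block + own tree block
  b_plot <- b[seq_len(nr)]
  eff <- matrix(0, n, nr, dimnames = list(NULL, varcomp$random))
  d_vec <- h_vec <- hi_vec <- y_vec <- numeric(n)
  pos <- 0L
  for (j in seq_len(J)) {
    tj <- trees[[j]]
    idx <- pos + seq_along(tj$h_i)
    eff[idx, ] <- matrix(b_plot + b[nr * j + seq_len(nr)], length(idx), nr, byrow = TRUE)
    d_vec[idx] <- tj$d; h_vec[idx] <- tj$h; hi_vec[idx] <- tj$h_i
    y_vec[idx] <- tj$d_i
    pos <- pos + length(idx)
  }

  f <- kozak_taper(d_vec, h_vec, hi_vec, params, effects = eff)
  G <- kozak_gradient(d_vec, h_vec, hi_vec, params, effects = eff,
                      wrt = varcomp$random)

  Z <- matrix(0, n, q)
  Z[, seq_len(nr)] <- G
  R <- matrix(0, n, n)
  pos <- 0L
  for (j in seq_len(J)) {
    tj <- trees[[j]]
    idx <- pos + seq_along(tj$h_i)
    Z[idx, nr * j + seq_len(nr)] <- G[idx, , drop = FALSE]
    g <- if (is.null(varcomp$delta)) 1 else variance_weights(tj$d, varcomp$delta)
    M <- if (is.null(varcomp$phi)) diag(length(idx)) else car1_matrix(tj$h_i, varcomp$phi)
    R[idx, idx] <- varcomp$sigma2 * g^2 * M
    pos <- pos + length(idx)
  }
  D <- matrix(0, q, q)
  D[seq_len(nr), seq_len(nr)] <- varcomp$D_plot
  for (j in seq_len(J)) D[nr * j + seq_len(nr), nr * j + seq_len(nr)] <- varcomp$D_tree
  list(D = D, Z = Z, R = R, resid = y_vec - f, f = f)
}

#' Assemble the block matrices of the calibration equations
#'
#' Builds the joint covariance `D` (block-diagonal: one plot block, one tree
#' block per tree), the random-effects design `Z` (plot columns repeated for
#' every row, tree blocks on the block diagonal, entries from
#' [kozak_gradient()] evaluated at the current effects), the residual
#' covariance `R` and the residual vector for the trees of one plot.
#'
#' @param model a mixed-effects fit from [taper_fit()].
#' @param newdata a `taper_data` object holding the calibration observations
#'   of the trees of one plot.
#' @param effects optional stacked effect vector
#'   `(b_plot, b_tree_1, ..., b_tree_J)` at which to evaluate; defaults to 0.
#' @return a list with components `D`, `Z`, `R`, `resid`, `f` and `trees`
#'   (the tree identifiers, giving the column blocks of `Z`).
#' @export
calibration_system <- function(model, newdata, effects = NULL) {
  stopifnot(inherits(model, "taper_fit"))
  if (is.null(model$varcomp)) stop("model carries no variance components")
  newdata <- if (inherits(newdata, "taper_data")) newdata else taper_data(newdata)
  if (length(unique(newdata$plot)) != 1L)
    stop("calibration observations must belong to a single plot")
  plot_rows <- .plot_structure(newdata)[[1L]]
  nr <- length(model$varcomp$random)
  q <- nr * (1L + length(plot_rows$trees))
  if (is.null(effects)) effects <- numeric(q)
  sys <- .assemble_system(model$params, model$varcomp, plot_rows, effects)
  sys$trees <- vapply(plot_rows$trees, function(t) t$tree, "")
  sys
}

# Split a taper_data into the nested per-plot / per-tree structure used by the
# fitting and calibration internals.
.plot_structure <- function(data) {
  plots <- split(seq_len(nrow(data)), data$plot)
  lapply(plots, function(ip) {
    sub <- data[ip, , drop = FALSE]
    trees <- split(seq_len(nrow(sub)), sub$tree)
    list(plot = sub$plot[1L],
         rows = ip,
         trees = lapply(trees, function(it) {
           tr <- sub[it, , drop = FALSE]
           list(tree = tr$tree[1L], d = tr$d[1L], h = tr$h[1L],
                h_i = tr$h_i, d_i = tr$d_i, rows = ip[it])
         }))
  })
}
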