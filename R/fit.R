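# Fixed-effects (OLS, GLS) and two-level FOCE mixed-effects estimation.

#' Control settings for taper model fitting
#'
#' @param pnls_tol relative tolerance of the penalized nonlinear least-squares
#'   objective (inner step of FOCE).
#' @param pnls_maxit maximum inner Gauss-Newton iterations.
#' @param outer_tol relative tolerance on the (RE)ML objective between outer
#'   FOCE iterations.
#' @param outer_abs_tol additional absolute tolerance on the -2 log-likelihood
#'   change; protects against endless oscillation at machine-level changes.
#' @param outer_maxit maximum outer FOCE iterations.
#' @param gn_tol,gn_maxit tolerance and iteration cap of the Gauss-Newton
#'   steps for fixed-effects-only fits.
#' @param optim_maxit iteration cap of the variance-parameter optimizer.
#' @param verbose print progress of the outer iterations.
#' @return a list of settings for [taper_fit()].
#' @export
taper_control <- function(pnls_tol = 1e-10, pnls_maxit = 50L,
                          outer_tol = 1e-8, outer_abs_tol = 1e-6,
                          outer_maxit = 200L,
                          gn_tol = 1e-12, gn_maxit = 200L,
                          optim_maxit = 200L, verbose = FALSE) {
  list(pnls_tol = pnls_tol, pnls_maxit = pnls_maxit, outer_tol = outer_tol,
       outer_abs_tol = outer_abs_tol, outer_maxit = outer_maxit,
       gn_tol = gn_tol, gn_maxit = gn_maxit, optim_maxit = optim_maxit,
       verbose = verbose)
}

# ---- prepared fitting structure ---------------------------------------------

.fit_structure <- function(data) {
  stopifnot(inherits(data, "taper_data"))
  n <- nrow(data)
  key <- paste(data$plot, data$tree, sep = "::")
  plots <- split(seq_len(n), data$plot)
  pl <- lapply(plots, function(rows) {
    sub_tree <- split(rows, key[rows])
    trees <- lapply(sub_tree, function(tr) {
      list(rows = tr, local = match(tr, rows), d = data$d[tr[1L]],
           h_i = data$h_i[tr], dist = abs(outer(data$h_i[tr], data$h_i[tr], "-")))
    })
    list(rows = rows, trees = trees)
  })
  list(n = n, y = data$d_i, d = data$d, h = data$h, h_i = data$h_i,
       plot_of_row = match(data$plot, names(plots)),
       tree_of_row = match(key, unique(key)),
       plot_ids = names(plots), tree_ids = unique(key), plots = pl)
}

# Finite-difference Jacobian of the taper prediction w.r.t. selected
# coefficients, at a full n x 9 coefficient matrix.
.fd_jacobian <- function(d, h, h_i, theta, wrt) {
  G <- matrix(0, length(h_i), length(wrt), dimnames = list(NULL, wrt))
  for (k in seq_along(wrt)) {
    j <- match(wrt[k], .kozak_names)
    step <- 1e-6 * pmax(1, abs(theta[, j]))
    tp <- theta; tp[, j] <- tp[, j] + step
    tm <- theta; tm[, j] <- tm[, j] - step
    G[, k] <- (.kozak_eval(d, h, h_i, tp) - .kozak_eval(d, h, h_i, tm)) / (2 * step)
  }
  G
}

.eff_rows <- function(fd, b_plot, b_tree, random) {
  eff <- b_plot[fd$plot_of_row, , drop = FALSE] +
    b_tree[fd$tree_of_row, , drop = FALSE]
  colnames(eff) <- random
  eff
}

# ---- variance-parameter packing ---------------------------------------------
# th = (log-chol D*_plot, log-chol D*_tree, delta?, logit phi?), everything on
# the sigma^2-relative scale (D* = D / sigma^2, R* = R / sigma^2).

.th_template <- function(nr, variance, car1) {
  nt <- .n_theta(nr)
  list(nr = nr, nt = nt, variance = variance, car1 = car1,
       length = 2L * nt + variance + car1)
}

.th_init <- function(tmpl) {
  one <- c(rep(log(0.1), tmpl$nr), rep(0, tmpl$nt - tmpl$nr))
  th <- c(one, one)
  if (tmpl$variance) th <- c(th, 0.5)
  if (tmpl$car1) th <- c(th, 0)
  th
}

.th_bounds <- function(tmpl) {
  one <- c(rep(-12, tmpl$nr), rep(-10, tmpl$nt - tmpl$nr))
  lo <- c(one, one); hi <- c(rep(4, tmpl$nr), rep(10, tmpl$nt - tmpl$nr))
  hi <- c(hi, hi)
  if (tmpl$variance) { lo <- c(lo, -3); hi <- c(hi, 3) }
  if (tmpl$car1) { lo <- c(lo, -7); hi <- c(hi, 7) }
  list(lower = lo, upper = hi)
}

.th_unpack <- function(th, tmpl) {
  nt <- tmpl$nt; nr <- tmpl$nr
  Lp <- .theta_chol(th[seq_len(nt)], nr)
  Lt <- .theta_chol(th[nt + seq_len(nt)], nr)
  pos <- 2L * nt
  delta <- if (tmpl$variance) th[pos + 1L] else NULL
  if (tmpl$variance) pos <- pos + 1L
  phi <- if (tmpl$car1) stats::plogis(th[pos + 1L]) else NULL
  list(Lp = Lp, Lt = Lt, delta = delta, phi = phi)
}

.theta_chol <- function(theta, k) {
  L <- matrix(0, k, k)
  diag(L) <- exp(theta[seq_len(k)])
  if (k > 1L) L[lower.tri(L)] <- theta[-seq_len(k)]
  L
}

# Per-tree residual scale/correlation factors at given (delta, phi):
# returns list per plot of list per tree with g (scalar) and U (chol of M, or
# NULL for identity).
.resid_factors <- function(fd, delta, phi) {
  lapply(fd$plots, function(pl) {
    lapply(pl$trees, function(tr) {
      list(g = if (is.null(delta)) 1 else tr$d^delta,
           U = if (is.null(phi)) NULL else chol(phi^tr$dist))
    })
  })
}

.whiten <- function(v, rf) {
  if (!is.null(rf$U)) v <- backsolve(rf$U, v, transpose = TRUE)
  v / rf$g
}

# log|R*_i| contribution of one tree (R* = g^2 M)
.logdet_tree <- function(rf, nij) {
  2 * nij * log(rf$g) + if (is.null(rf$U)) 0 else 2 * sum(log(diag(rf$U)))
}

# Build V_i = Z_i D* Z_i' + R*_i for one plot (sigma^2-relative scale).
.plot_V <- function(pl, Zr_i, vc, rfs_i) {
  n_i <- length(pl$rows)
  V <- tcrossprod(Zr_i %*% vc$Lp)
  for (j in seq_along(pl$trees)) {
    tr <- pl$trees[[j]]
    idx <- tr$local
    Zt <- Zr_i[idx, , drop = FALSE]
    rf <- rfs_i[[j]]
    Rj <- if (is.null(rf$U)) diag(rf$g^2, length(idx)) else rf$g^2 * crossprod(rf$U)
    V[idx, idx] <- V[idx, idx] + tcrossprod(Zt %*% vc$Lt) + Rj
  }
  V
}

# ---- profiled (RE)ML of the working linear mixed model ----------------------

# lin: list(w, X, Zr) at the current linearization point.
.nll_theta <- function(th, tmpl, fd, lin, criterion, details = FALSE) {
  vc <- .th_unpack(th, tmpl)
  rfs <- .resid_factors(fd, vc$delta, vc$phi)
  p <- ncol(lin$X)
  xtx <- matrix(0, p, p); xtw <- numeric(p)
  wtw <- 0; logdet <- 0
  for (i in seq_along(fd$plots)) {
    pl <- fd$plots[[i]]
    Zr_i <- lin$Zr[pl$rows, , drop = FALSE]
    V <- .plot_V(pl, Zr_i, vc, rfs[[i]])
    C <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(C)) return(if (details) NULL else 1e10)
    logdet <- logdet + 2 * sum(log(diag(C)))
    S <- backsolve(C, cbind(lin$w[pl$rows], lin$X[pl$rows, , drop = FALSE]),
                   transpose = TRUE)
    wtw <- wtw + sum(S[, 1L]^2)
    xtx <- xtx + crossprod(S[, -1L, drop = FALSE])
    xtw <- xtw + crossprod(S[, -1L, drop = FALSE], S[, 1L])[, 1L]
  }
  beta <- tryCatch(solve(xtx, xtw), error = function(e) NULL)
  if (is.null(beta)) return(if (details) NULL else 1e10)
  RSS <- max(wtw - sum(xtw * beta), 1e-300)
  N <- fd$n
  if (criterion == "ML") {
    sigma2 <- RSS / N
    val <- N * log(2 * pi * sigma2) + logdet + N
  } else {
    sigma2 <- RSS / (N - p)
    val <- (N - p) * log(2 * pi * sigma2) + logdet +
      determinant(xtx, logarithm = TRUE)$modulus + (N - p)
  }
  val <- as.numeric(val)
  if (!is.finite(val)) return(if (details) NULL else 1e10)
  if (details) list(value = val, beta = beta, sigma2 = sigma2, xtx = xtx,
                    vc = vc) else val
}

# ---- penalized nonlinear least squares (inner FOCE step) --------------------

# Joint Gauss-Newton update of (beta, b) at fixed variance parameters,
# implemented through the mixed-model equations: each step solves the
# linearized system via per-plot V_i = Z_i D* Z_i' + R*_i and updates the
# effects with the EBLUP formula b_i = D* Z_i' V_i^-1 (u_i - X_i dbeta).
.pnls <- function(fd, params, b_plot, b_tree, vc, rfs, active, random, control) {
  nr <- length(random)
  Dp_inv <- chol2inv(t(vc$Lp))  # (L L')^-1 from lower-tri L
  Dt_inv <- chol2inv(t(vc$Lt))

  pen_obj <- function(params, b_plot, b_tree) {
    if (!is.finite(params["a0"]) || params["a0"] <= 0) return(Inf)
    eff <- .eff_rows(fd, b_plot, b_tree, random)
    f <- .kozak_eval(fd$d, fd$h, fd$h_i, .theta_matrix(params, eff, fd$n))
    r <- fd$y - f
    obj <- 0
    for (i in seq_along(fd$plots)) {
      pl <- fd$plots[[i]]
      for (j in seq_along(pl$trees)) {
        tr <- pl$trees[[j]]
        obj <- obj + sum(.whiten(r[tr$rows], rfs[[i]][[j]])^2)
      }
      obj <- obj + drop(t(b_plot[i, ]) %*% Dp_inv %*% b_plot[i, ])
    }
    for (t in seq_len(nrow(b_tree)))
      obj <- obj + drop(t(b_tree[t, ]) %*% Dt_inv %*% b_tree[t, ])
    obj
  }

  obj <- pen_obj(params, b_plot, b_tree)
  converged <- FALSE
  for (it in seq_len(control$pnls_maxit)) {
    eff <- .eff_rows(fd, b_plot, b_tree, random)
    theta <- .theta_matrix(params, eff, fd$n)
    f <- .kozak_eval(fd$d, fd$h, fd$h_i, theta)
    X <- .fd_jacobian(fd$d, fd$h, fd$h_i, theta, active)
    Zr <- if (all(random %in% active)) X[, random, drop = FALSE]
          else .fd_jacobian(fd$d, fd$h, fd$h_i, theta, random)
    u <- (fd$y - f) + rowSums(Zr * eff[, random, drop = FALSE])

    p <- length(active)
    xtx <- matrix(0, p, p); xtu <- numeric(p)
    chols <- vector("list", length(fd$plots))
    vc_small <- list(Lp = vc$Lp, Lt = vc$Lt)
    for (i in seq_along(fd$plots)) {
      pl <- fd$plots[[i]]
      V <- .plot_V(pl, Zr[pl$rows, , drop = FALSE], vc_small, rfs[[i]])
      C <- chol(V)
      chols[[i]] <- C
      S <- backsolve(C, cbind(u[pl$rows], X[pl$rows, , drop = FALSE]),
                     transpose = TRUE)
      xtx <- xtx + crossprod(S[, -1L, drop = FALSE])
      xtu <- xtu + crossprod(S[, -1L, drop = FALSE], S[, 1L])[, 1L]
    }
    dbeta <- solve(xtx, xtu)

    Dp <- tcrossprod(vc$Lp); Dt <- tcrossprod(vc$Lt)
    b_plot_new <- b_plot; b_tree_new <- b_tree
    for (i in seq_along(fd$plots)) {
      pl <- fd$plots[[i]]
      Zr_i <- Zr[pl$rows, , drop = FALSE]
      res <- u[pl$rows] - X[pl$rows, , drop = FALSE] %*% dbeta
      t_i <- backsolve(chols[[i]], backsolve(chols[[i]], res, transpose = TRUE))
      b_plot_new[i, ] <- Dp %*% crossprod(Zr_i, t_i)
      for (j in seq_along(pl$trees)) {
        tr <- pl$trees[[j]]
        tree_idx <- fd$tree_of_row[tr$rows[1L]]
        b_tree_new[tree_idx, ] <- Dt %*% crossprod(Zr_i[tr$local, , drop = FALSE],
                                                   t_i[tr$local])
      }
    }

    # step-halving on the penalized objective
    step <- 1; improved <- FALSE
    for (half in 1:20) {
      cand_params <- params
      cand_params[active] <- cand_params[active] + step * dbeta
      cand_bp <- b_plot + step * (b_plot_new - b_plot)
      cand_bt <- b_tree + step * (b_tree_new - b_tree)
      cand_obj <- pen_obj(cand_params, cand_bp, cand_bt)
      if (is.finite(cand_obj) && cand_obj <= obj * (1 + 1e-12)) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    params <- cand_params; b_plot <- cand_bp; b_tree <- cand_bt
    if (abs(obj - cand_obj) < control$pnls_tol * (abs(obj) + 1e-10)) {
      obj <- cand_obj; converged <- TRUE; break
    }
    obj <- cand_obj
  }
  list(params = params, b_plot = b_plot, b_tree = b_tree, obj = obj,
       converged = converged)
}

# Linearization pieces at (params, b): working response w = y - f + X beta + Z b.
.linearize <- function(fd, params, b_plot, b_tree, active, random) {
  eff <- .eff_rows(fd, b_plot, b_tree, random)
  theta <- .theta_matrix(params, eff, fd$n)
  f <- .kozak_eval(fd$d, fd$h, fd$h_i, theta)
  X <- .fd_jacobian(fd$d, fd$h, fd$h_i, theta, active)
  Zr <- if (all(random %in% active)) X[, random, drop = FALSE]
        else .fd_jacobian(fd$d, fd$h, fd$h_i, theta, random)
  w <- (fd$y - f) + drop(X %*% params[active]) +
    rowSums(Zr * eff[, random, drop = FALSE])
  list(w = w, X = X, Zr = Zr, f = f)
}

# ---- Gauss-Newton for fixed-effects-only fits -------------------------------

.gn_fixed <- function(fd, params, active, rfs, control) {
  wsse <- function(params) {
    if (!is.finite(params["a0"]) || params["a0"] <= 0) return(Inf)
    f <- .kozak_eval(fd$d, fd$h, fd$h_i, .theta_matrix(params, NULL, fd$n))
    r <- fd$y - f
    s <- 0
    for (i in seq_along(fd$plots)) for (j in seq_along(fd$plots[[i]]$trees)) {
      tr <- fd$plots[[i]]$trees[[j]]
      s <- s + sum(.whiten(r[tr$rows], rfs[[i]][[j]])^2)
    }
    s
  }
  obj <- wsse(params)
  converged <- FALSE
  for (it in seq_len(control$gn_maxit)) {
    theta <- .theta_matrix(params, NULL, fd$n)
    f <- .kozak_eval(fd$d, fd$h, fd$h_i, theta)
    X <- .fd_jacobian(fd$d, fd$h, fd$h_i, theta, active)
    r <- fd$y - f
    Xw <- X; rw <- r
    for (i in seq_along(fd$plots)) for (j in seq_along(fd$plots[[i]]$trees)) {
      tr <- fd$plots[[i]]$trees[[j]]
      rf <- rfs[[i]][[j]]
      Xw[tr$rows, ] <- .whiten(X[tr$rows, , drop = FALSE], rf)
      rw[tr$rows] <- .whiten(r[tr$rows], rf)
    }
    qr_ <- qr(Xw)
    if (qr_$rank < length(active))
      stop("model is underdetermined: rank-deficient Jacobian (",
           qr_$rank, " < ", length(active), " free parameters)")
    dbeta <- qr.coef(qr_, rw)
    step <- 1; improved <- FALSE
    for (half in 1:25) {
      cand <- params
      cand[active] <- cand[active] + step * dbeta
      cand_obj <- wsse(cand)
      if (is.finite(cand_obj) && cand_obj <= obj * (1 + 1e-13)) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    params <- cand
    if (abs(obj - cand_obj) < control$gn_tol * (abs(obj) + 1e-10)) {
      obj <- cand_obj; converged <- TRUE; break
    }
    obj <- cand_obj
  }
  # standard errors from the whitened Jacobian at the solution
  theta <- .theta_matrix(params, NULL, fd$n)
  X <- .fd_jacobian(fd$d, fd$h, fd$h_i, theta, active)
  for (i in seq_along(fd$plots)) for (j in seq_along(fd$plots[[i]]$trees)) {
    tr <- fd$plots[[i]]$trees[[j]]
    X[tr$rows, ] <- .whiten(X[tr$rows, , drop = FALSE], rfs[[i]][[j]])
  }
  list(params = params, sse = obj, xtx = crossprod(X), converged = converged)
}

.logdet_R <- function(fd, rfs) {
  s <- 0
  for (i in seq_along(fd$plots)) for (j in seq_along(fd$plots[[i]]$trees)) {
    tr <- fd$plots[[i]]$trees[[j]]
    s <- s + .logdet_tree(rfs[[i]][[j]], length(tr$rows))
  }
  s
}

# ---- main fitting function --------------------------------------------------

#' Fit the taper equation to hierarchical stem data
#'
#' Fits the variable-exponent taper equation by one of three methods:
#' \describe{
#'   \item{`"OLS"`}{nonlinear ordinary least squares (all observations
#'     weighted equally, no correlation).}
#'   \item{`"GLS"`}{generalized nonlinear least squares by maximum
#'     likelihood, with an optional power-of-DBH variance function
#'     (`variance = TRUE`: `sd = sigma * d^delta`) and optional within-tree
#'     CAR(1) correlation (`car1 = TRUE`); `delta` and `phi` are estimated
#'     jointly with the coefficients.}
#'   \item{`"FOCE"`}{two-level nonlinear mixed-effects estimation with
#'     bivariate (or general) random effects on the parameters named in
#'     `random` at both plot and tree level, by first-order conditional
#'     expectation (FOCE) linearization: a penalized nonlinear least-squares
#'     step for the fixed parameters and all subject EBLUPs alternates with
#'     (RE)ML maximization of the profiled likelihood of the working linear
#'     mixed model, linearized about the current EBLUPs, until the objective
#'     stabilizes.}
#' }
#'
#' @param data a `taper_data` object.
#' @param method `"OLS"`, `"GLS"` or `"FOCE"`.
#' @param random parameters carrying plot- and tree-level random effects
#'   (FOCE only); must be a subset of `active`.
#' @param criterion `"REML"` or `"ML"` (FOCE only; GLS and OLS maximize the
#'   ordinary likelihood).
#' @param variance logical: include the power-of-DBH variance function
#'   (GLS/FOCE).
#' @param car1 logical: include within-tree CAR(1) correlation (GLS/FOCE).
#' @param active names of the coefficients kept in the model; dropped
#'   coefficients are fixed at 0.
#' @param start named starting values; defaults to
#'   `a0 = 1, a1 = 1, a2 = 0, b1..b6 = 0.1` for OLS/GLS and to the OLS
#'   estimates for FOCE.
#' @param control see [taper_control()].
#' @return an object of class `taper_fit` with components `params`, `se`,
#'   `varcomp`, `eblups`, `loglik`, `aic`, `bic`, `fitted`, `residuals`,
#'   `converged` among others; see also the `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `simulate` and `anova` methods.
#' @export
taper_fit <- function(data, method = c("OLS", "GLS", "FOCE"),
                      random = c("a1", "b3"),
                      criterion = c("REML", "ML"),
                      variance = TRUE, car1 = FALSE,
                      active = .kozak_names, start = NULL,
                      control = taper_control()) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  cl <- match.call()
  data <- if (inherits(data, "taper_data")) data else taper_data(data)
  fd <- .fit_structure(data)
  active <- match.arg(active, .kozak_names, several.ok = TRUE)
  if (!"a0" %in% active) stop("'a0' must stay in the model")
  p <- length(active)
  if (fd$n <= p) stop("underdetermined: ", fd$n, " observations for ", p,
                      " free parameters")
  default_start <- kozak_params(a0 = 1, a1 = 1, a2 = 0, b1 = 0.1, b2 = 0.1,
                                b3 = 0.1, b4 = 0.1, b5 = 0.1, b6 = 0.1)
  params <- default_start
  params[setdiff(.kozak_names, active)] <- 0
  if (!is.null(start)) {
    st <- .full_params(start)
    params[active] <- st[active]
    params[setdiff(.kozak_names, active)] <- 0
  }

  out <- switch(method,
    OLS = .fit_ols(fd, params, active, control),
    GLS = .fit_gls(fd, params, active, variance, car1, control),
    FOCE = .fit_foce(fd, params, active, random, criterion, variance, car1,
                     control, start_given = !is.null(start)))
  out$call <- cl
  out$data <- data
  out$active <- active
  out$n_obs <- fd$n
  out$n_fixed <- p
  out$aic <- -2 * out$loglik + 2 * out$df
  out$bic <- -2 * out$loglik + log(fd$n) * out$df
  class(out) <- "taper_fit"
  out
}

.fit_ols <- function(fd, params, active, control) {
  rfs <- .resid_factors(fd, NULL, NULL)
  gn <- .gn_fixed(fd, params, active, rfs, control)
  n <- fd$n; p <- length(active)
  sigma2_ml <- gn$sse / n
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  vcov <- gn$sse / (n - p) * solve(gn$xtx)
  dimnames(vcov) <- list(active, active)
  list(method = "OLS", criterion = "ML", params = gn$params,
       se = sqrt(diag(vcov)), vcov = vcov,
       sigma2 = gn$sse / (n - p), varcomp = NULL, random = character(),
       eblups = NULL, loglik = loglik, df = p + 1L,
       fitted = .kozak_eval(fd$d, fd$h, fd$h_i, .theta_matrix(gn$params, NULL, fd$n)),
       residuals = fd$y - .kozak_eval(fd$d, fd$h, fd$h_i,
                                      .theta_matrix(gn$params, NULL, fd$n)),
       converged = gn$converged, variance = FALSE, car1 = FALSE)
}

.fit_gls <- function(fd, params, active, variance, car1, control) {
  n <- fd$n; p <- length(active)
  env <- new.env()
  env$params <- params
  nll <- function(th) {
    delta <- if (variance) th[1L] else NULL
    phi <- if (car1) stats::plogis(th[length(th)]) else NULL
    rfs <- .resid_factors(fd, delta, phi)
    gn <- tryCatch(.gn_fixed(fd, env$params, active, rfs, control),
                   error = function(e) NULL)
    if (is.null(gn)) return(1e10)
    env$params <- gn$params   # warm start the next evaluation
    sigma2 <- gn$sse / n
    val <- n * log(2 * pi * sigma2) + .logdet_R(fd, rfs) + n
    if (!is.finite(val)) 1e10 else val
  }
  if (variance || car1) {
    th0 <- c(if (variance) 0.5 else NULL, if (car1) 0 else NULL)
    lo <- c(if (variance) -3 else NULL, if (car1) -7 else NULL)
    hi <- c(if (variance) 3 else NULL, if (car1) 7 else NULL)
    opt <- stats::optim(th0, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = control$optim_maxit))
    th <- opt$par
    conv_outer <- opt$convergence == 0L
  } else {
    th <- numeric(); conv_outer <- TRUE
  }
  delta <- if (variance) th[1L] else NULL
  phi <- if (car1) stats::plogis(th[length(th)]) else NULL
  rfs <- .resid_factors(fd, delta, phi)
  gn <- .gn_fixed(fd, env$params, active, rfs, control)
  sigma2_ml <- gn$sse / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + .logdet_R(fd, rfs) + n)
  vcov <- gn$sse / (n - p) * solve(gn$xtx)
  dimnames(vcov) <- list(active, active)
  f <- .kozak_eval(fd$d, fd$h, fd$h_i, .theta_matrix(gn$params, NULL, fd$n))
  list(method = "GLS", criterion = "ML", params = gn$params,
       se = sqrt(diag(vcov)), vcov = vcov,
       sigma2 = gn$sse / (n - p), delta = delta, phi = phi, varcomp = NULL,
       random = character(), eblups = NULL, loglik = loglik,
       df = p + 1L + variance + car1,
       fitted = f, residuals = fd$y - f,
       converged = gn$converged && conv_outer, variance = variance, car1 = car1)
}

.fit_foce <- function(fd, params, active, random, criterion, variance, car1,
                      control, start_given = FALSE) {
  random <- match.arg(random, .kozak_names, several.ok = TRUE)
  if (!all(random %in% active))
    stop("'random' must be a subset of the active parameters")
  nr <- length(random)
  if (!start_given) {
    # OLS estimates are a robust, reproducible starting point
    ols <- .fit_ols(fd, params, active, control)
    params <- ols$params
  }
  tmpl <- .th_template(nr, variance, car1)
  th <- .th_init(tmpl)
  bounds <- .th_bounds(tmpl)
  n_plots <- length(fd$plots)
  n_trees <- length(fd$tree_ids)
  b_plot <- matrix(0, n_plots, nr)
  b_tree <- matrix(0, n_trees, nr)

  obj_old <- Inf
  converged <- FALSE
  iterations <- 0L
  opt_value <- NA_real_
  for (outer in seq_len(control$outer_maxit)) {
    iterations <- outer
    vc <- .th_unpack(th, tmpl)
    rfs <- .resid_factors(fd, vc$delta, vc$phi)
    pn <- .pnls(fd, params, b_plot, b_tree, vc, rfs, active, random, control)
    params <- pn$params; b_plot <- pn$b_plot; b_tree <- pn$b_tree

    lin <- .linearize(fd, params, b_plot, b_tree, active, random)
    opt <- stats::optim(th, .nll_theta, tmpl = tmpl, fd = fd, lin = lin,
                        criterion = criterion, method = "L-BFGS-B",
                        lower = bounds$lower, upper = bounds$upper,
                        control = list(maxit = control$optim_maxit))
    th <- opt$par
    opt_value <- opt$value
    if (control$verbose)
      message(sprintf("outer %d: -2logLik = %.6f", outer, opt_value))
    if (is.finite(obj_old) &&
        (abs(obj_old - opt_value) < control$outer_tol * (abs(obj_old) + 1e-10) ||
         abs(obj_old - opt_value) < control$outer_abs_tol)) {
      converged <- TRUE
      break
    }
    obj_old <- opt_value
  }
  if (!converged)
    warning("FOCE did not reach the outer tolerance in ", control$outer_maxit,
            " iterations; returning the current iterate")

  # final inner step at the converged variance parameters, then report the
  # likelihood pieces of the working model at that point
  vc <- .th_unpack(th, tmpl)
  rfs <- .resid_factors(fd, vc$delta, vc$phi)
  pn <- .pnls(fd, params, b_plot, b_tree, vc, rfs, active, random, control)
  params <- pn$params; b_plot <- pn$b_plot; b_tree <- pn$b_tree
  lin <- .linearize(fd, params, b_plot, b_tree, active, random)
  det <- .nll_theta(th, tmpl, fd, lin, criterion, details = TRUE)
  if (is.null(det)) stop("FOCE failed to evaluate the likelihood at the solution")
  sigma2 <- det$sigma2
  D_plot <- sigma2 * tcrossprod(det$vc$Lp)
  D_tree <- sigma2 * tcrossprod(det$vc$Lt)
  dimnames(D_plot) <- dimnames(D_tree) <- list(random, random)
  varcomp <- taper_varcomp(random, D_plot, D_tree, sigma2,
                           delta = det$vc$delta, phi = det$vc$phi)
  vcov <- sigma2 * solve(det$xtx)
  dimnames(vcov) <- list(active, active)
  p <- length(active)
  df <- p + 1L + variance + car1 + 2L * .n_theta(nr)
  rownames(b_plot) <- fd$plot_ids
  rownames(b_tree) <- fd$tree_ids
  colnames(b_plot) <- colnames(b_tree) <- random
  eff <- .eff_rows(fd, b_plot, b_tree, random)
  f <- .kozak_eval(fd$d, fd$h, fd$h_i, .theta_matrix(params, eff, fd$n))
  list(method = paste0("FOCE-", criterion), criterion = criterion,
       params = params, se = sqrt(diag(vcov)), vcov = vcov,
       sigma2 = sigma2, varcomp = varcomp, random = random,
       eblups = list(plot = b_plot, tree = b_tree),
       loglik = -opt_value / 2, df = df,
       fitted = f, residuals = fd$y - f,
       converged = converged, iterations = iterations,
       variance = variance, car1 = car1)
}
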