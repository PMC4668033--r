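# S3 methods for fitted taper models.

#' @export
print.taper_fit <- function(x, digits = 4L, ...) {
  cat("Variable-exponent taper model, method ", x$method, "\n", sep = "")
  cat(sprintf("  logLik %.2f  AIC %.1f  BIC %.1f  (n = %d, k = %d)\n",
              x$loglik, x$aic, x$bic, x$n_obs, x$df))
  cat("Coefficients:\n")
  print(signif(x$params[x$active], digits))
  if (!is.null(x$varcomp)) print(x$varcomp)
  else if (!is.null(x$sigma2)) {
    cat(sprintf("Residual variance sigma2 = %.4g", x$sigma2))
    if (!is.null(x$delta)) cat(sprintf("; delta = %.4g", x$delta))
    if (!is.null(x$phi)) cat(sprintf("; CAR(1) phi = %.4g", x$phi))
    cat("\n")
  }
  if (!isTRUE(x$converged)) cat("** fit did not converge **\n")
  invisible(x)
}

#' @export
summary.taper_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$params[object$active],
               `Std.Error` = object$se[object$active],
               `t value` = object$params[object$active] / object$se[object$active])
  structure(list(fit = object, coefficients = tab), class = "summary.taper_fit")
}

#' @export
print.summary.taper_fit <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficient table:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
coef.taper_fit <- function(object, ...) object$params[object$active]

#' @export
vcov.taper_fit <- function(object, ...) object$vcov

#' @export
logLik.taper_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.taper_fit <- function(object, ...) object$fitted

#' @export
residuals.taper_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "pearson") {
    sigma2 <- if (!is.null(object$varcomp)) object$varcomp$sigma2 else object$sigma2
    delta <- if (!is.null(object$varcomp)) object$varcomp$delta else object$delta
    g <- if (is.null(delta)) 1 else variance_weights(object$data$d, delta)
    r <- r / (sqrt(sigma2) * g)
  }
  r
}

# Random-effect offsets per row of `data` for a requested prediction level.
.level_effects <- function(object, data, level) {
  if (level == "mean") return(NULL)
  if (is.null(object$eblups))
    stop("model has no random effects; only level = \"mean\" is available")
  nr <- length(object$random)
  eff <- matrix(0, nrow(data), nr, dimnames = list(NULL, object$random))
  ip <- match(data$plot, rownames(object$eblups$plot))
  if (anyNA(ip))
    stop("unknown plot id(s): ",
         paste(unique(data$plot[is.na(ip)]), collapse = ", "))
  eff <- eff + object$eblups$plot[ip, , drop = FALSE]
  if (level == "tree") {
    key <- paste(data$plot, data$tree, sep = "::")
    it <- match(key, rownames(object$eblups$tree))
    if (anyNA(it))
      stop("unknown tree id(s): ",
           paste(unique(key[is.na(it)]), collapse = ", "))
    eff <- eff + object$eblups$tree[it, , drop = FALSE]
  }
  colnames(eff) <- object$random
  eff
}

#' Predict diameters or volumes from a fitted taper model
#'
#' @param object a `taper_fit` object.
#' @param newdata a `taper_data` object (or data frame with columns `plot`,
#'   `tree`, `d`, `h`, `h_i`); defaults to the fitting data.
#' @param type `"diameter"` for section diameters (cm) at the `h_i` of each
#'   row, or `"volume"` for one integrated stem volume (m^3) per tree.
#' @param level `"mean"` (fixed parameters only), `"plot"` (plot-level
#'   EBLUPs added) or `"tree"` (plot- plus tree-level EBLUPs); subjects must
#'   belong to the fitting data for levels other than `"mean"`.
#' @param lower,upper integration bounds for volumes; default `0` to `h`.
#' @param ... unused.
#' @return a numeric vector (diameters) or a per-tree data frame with a `v`
#'   column (volumes).
#' @export
predict.taper_fit <- function(object, newdata = NULL,
                              type = c("diameter", "volume"),
                              level = c("mean", "plot", "tree"),
                              lower = 0, upper = NULL, ...) {
  type <- match.arg(type)
  level <- match.arg(level)
  data <- if (is.null(newdata)) object$data else newdata
  if (!is.data.frame(data)) stop("'newdata' must be a data frame")
  eff <- .level_effects(object, data, level)
  if (type == "diameter")
    return(kozak_taper(data$d, data$h, data$h_i, object$params, effects = eff))
  key <- paste(data$plot, data$tree, sep = "::")
  idx <- split(seq_len(nrow(data)), key)
  rows <- lapply(idx, function(i) {
    up <- if (is.null(upper)) data$h[i[1L]] else upper
    e <- if (is.null(eff)) NULL else eff[i[1L], ]
    data.frame(plot = data$plot[i[1L]], tree = data$tree[i[1L]],
               v = stem_volume(object$params, data$d[i[1L]], data$h[i[1L]],
                               lower = lower, upper = up, effects = e),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
simulate.taper_fit <- function(object, nsim = 1, seed = NULL, ...) {
  runner <- function() {
    data <- object$data
    out <- vector("list", nsim)
    for (s in seq_len(nsim)) {
      if (is.null(object$varcomp)) {
        mu <- kozak_taper(data$d, data$h, data$h_i, object$params)
        delta <- object$delta
        g <- if (is.null(delta)) 1 else variance_weights(data$d, delta)
        out[[s]] <- pmax(0, mu + stats::rnorm(nrow(data), 0, sqrt(object$sigma2) * g))
      } else {
        vc <- object$varcomp
        plots <- unique(data$plot)
        key <- paste(data$plot, data$tree, sep = "::")
        trees <- unique(key)
        bp <- .rmvnorm(length(plots), vc$D_plot)
        bt <- .rmvnorm(length(trees), vc$D_tree)
        eff <- bp[match(data$plot, plots), , drop = FALSE] +
          bt[match(key, trees), , drop = FALSE]
        colnames(eff) <- vc$random
        mu <- kozak_taper(data$d, data$h, data$h_i, object$params, effects = eff)
        e <- numeric(nrow(data))
        for (tk in trees) {
          i <- which(key == tk)
          g <- if (is.null(vc$delta)) 1 else variance_weights(data$d[i[1L]], vc$delta)
          M <- if (is.null(vc$phi)) diag(length(i)) else car1_matrix(data$h_i[i], vc$phi)
          e[i] <- sqrt(vc$sigma2) * g * drop(t(chol(M)) %*% stats::rnorm(length(i)))
        }
        out[[s]] <- pmax(0, mu + e)
      }
    }
    stats::setNames(as.data.frame(out), paste0("sim_", seq_len(nsim)))
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' Compare fitted taper models
#'
#' Builds an information-criterion table for two or more fits of the same
#' data and runs sequential likelihood-ratio tests between consecutive
#' models (declared nested in the order given).  REML fits with different
#' fixed structures are refused for the LRT, since their restricted
#' likelihoods are not comparable.
#'
#' @param object,... two or more `taper_fit` objects on the same data.
#' @return a data frame of class `anova.taper_fit`.
#' @export
anova.taper_fit <- function(object, ...) {
  fits <- c(list(object), Filter(function(z) inherits(z, "taper_fit"), list(...)))
  labels <- c(deparse(substitute(object))[1L],
              vapply(substitute(list(...))[-1L], function(e) deparse(e)[1L], ""))
  labels <- labels[seq_along(fits)]
  n <- vapply(fits, function(f) f$n_obs, 1)
  if (length(unique(n)) != 1L)
    stop("models were fitted to different numbers of observations")
  tab <- data.frame(Model = labels,
                    Method = vapply(fits, function(f) f$method, ""),
                    df = vapply(fits, function(f) f$df, 1),
                    AIC = vapply(fits, function(f) f$aic, 1),
                    BIC = vapply(fits, function(f) f$bic, 1),
                    logLik = vapply(fits, function(f) f$loglik, 1),
                    stringsAsFactors = FALSE)
  if (length(fits) > 1L) {
    stat <- pval <- rep(NA_real_, length(fits))
    for (i in 2:length(fits)) {
      a <- fits[[i - 1L]]; b <- fits[[i]]
      reml <- grepl("REML", a$method) || grepl("REML", b$method)
      if (reml && !identical(sort(a$active), sort(b$active)))
        stop("refusing a likelihood-ratio test between REML fits with ",
             "different fixed structures; refit with criterion = \"ML\"")
      stat[i] <- abs(2 * (b$loglik - a$loglik))
      dfd <- abs(b$df - a$df)
      pval[i] <- if (dfd == 0L) {
        if (stat[i] < 1e-8) 1 else NA_real_
      } else stats::pchisq(stat[i], dfd, lower.tail = FALSE)
    }
    tab$L.Ratio <- stat
    tab$`p-value` <- pval
  }
  class(tab) <- c("anova", "data.frame")
  tab
}

#' Refit after dropping non-significant coefficients
#'
#' Removes active coefficients whose absolute t-ratio falls below `z`
#' (except `a0`, which anchors the allometric scale) and refits the model
#' with the same method and settings.
#'
#' @param object a `taper_fit` object.
#' @param z t-ratio threshold (default 1.96, the two-sided 5\% rule).
#' @return a new `taper_fit`, or the original object when all coefficients
#'   are significant.
#' @export
prune_insignificant <- function(object, z = 1.96) {
  stopifnot(inherits(object, "taper_fit"))
  t_ratio <- abs(object$params[object$active] / object$se[object$active])
  drop <- setdiff(object$active[t_ratio < z], c("a0", object$random))
  if (!length(drop)) return(object)
  keep <- setdiff(object$active, drop)
  method <- sub("-.*$", "", object$method)
  taper_fit(object$data, method = method,
            random = if (length(object$random)) object$random else c("a1", "b3"),
            criterion = if (identical(object$criterion, "REML")) "REML" else "ML",
            variance = isTRUE(object$variance), car1 = isTRUE(object$car1),
            active = keep, start = object$params)
}

#' @export
plot.taper_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$fitted, residuals(x, type = "pearson"),
                 xlab = "fitted diameter (cm)",
                 ylab = "standardized residual", main = x$method, ...)
  graphics::abline(h = 0, lty = 2)
  # profile of the median-DBH tree
  data <- x$data
  key <- paste(data$plot, data$tree, sep = "::")
  d_tree <- tapply(data$d, key, `[`, 1L)
  pick <- names(d_tree)[which.min(abs(d_tree - stats::median(d_tree)))]
  i <- which(key == pick)
  hh <- seq(0, data$h[i[1L]], length.out = 100L)
  graphics::plot(data$h_i[i], data$d_i[i], xlab = "section height (m)",
                 ylab = "diameter (cm)", main = paste("tree", pick))
  graphics::lines(hh, kozak_taper(data$d[i[1L]], data$h[i[1L]], hh, x$params))
  invisible(x)
}
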