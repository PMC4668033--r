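# Random-effect sensitivity: stem-taper envelopes from quantiles of the
# estimated random-effects distribution.

#' Stem-taper envelopes from random-effect quantiles
#'
#' For a probe tree of given DBH and total height, builds taper-curve bands
#' showing how much stem shapes vary across the estimated random-effects
#' distribution.
#'
#' In `mode = "separate"` each expanded parameter is varied on its own: its
#' effect is set to the normal quantile of the summed plot- plus tree-level
#' marginal variance (`Var = D_plot[r, r] + D_tree[r, r]`, a new tree being
#' the sum of two independent draws) while the other effects stay 0.  In
#' `mode = "joint"` effect vectors are drawn from
#' `N(0, D_plot + D_tree)` with the full covariance, every curve is
#' evaluated, and the band at each grid height is the pointwise empirical
#' quantile of the simulated curves — which is how correlation between
#' random effects shapes the envelope.
#'
#' @param model a mixed-effects `taper_fit`, or a coefficient set from
#'   [taper_coefs()] carrying variance components.
#' @param d,h probe-tree DBH (cm) and total height (m).
#' @param mode `"joint"` or `"separate"`.
#' @param levels lower tail probabilities of the bands (each band spans
#'   `(p, 1 - p)`); defaults to the 30-70, 10-90 and 1-99 bands.
#' @param grid section heights at which curves are evaluated.
#' @param n_draws,seed Monte-Carlo settings for the joint mode.
#' @return an object of class `taper_envelope`: a data frame with columns
#'   `mode`, `param` (`"joint"` in joint mode), `band`, `level`, `h_i`,
#'   `lower`, `upper`, plus the mean-response curve as attribute `m_curve`.
#' @export
taper_envelope <- function(model, d = 24, h = 14,
                           mode = c("joint", "separate"),
                           levels = c(0.30, 0.10, 0.01),
                           grid = seq(0, h, by = 0.1),
                           n_draws = 2000L, seed = 1L) {
  mode <- match.arg(mode)
  params <- .full_params(model$params)
  vc <- model$varcomp
  if (is.null(vc)) stop("variance components are required for an envelope")
  if (any(levels <= 0) || any(levels >= 1)) stop("'levels' must lie in (0, 1)")
  levels <- pmin(levels, 1 - levels)
  m_curve <- kozak_taper(d, h, grid, params)
  out <- list()
  if (mode == "separate") {
    for (r in vc$random) {
      sd_r <- sqrt(vc$D_plot[r, r] + vc$D_tree[r, r])
      for (p_lo in levels) {
        lo_eff <- stats::setNames(stats::qnorm(p_lo) * sd_r, r)
        hi_eff <- stats::setNames(stats::qnorm(1 - p_lo) * sd_r, r)
        lo <- kozak_taper(d, h, grid, params, effects = lo_eff)
        hi <- kozak_taper(d, h, grid, params, effects = hi_eff)
        out[[length(out) + 1L]] <- data.frame(
          mode = mode, param = r,
          band = sprintf("Q%g-%g", 100 * p_lo, 100 * (1 - p_lo)),
          level = p_lo, h_i = grid,
          lower = pmin(lo, hi), upper = pmax(lo, hi),
          stringsAsFactors = FALSE)
      }
    }
  } else {
    D <- vc$D_plot + vc$D_tree
    draws <- with_seed(seed, .rmvnorm(n_draws, D))
    colnames(draws) <- vc$random
    curves <- matrix(0, n_draws, length(grid))
    for (s in seq_len(n_draws))
      curves[s, ] <- kozak_taper(d, h, grid, params, effects = draws[s, ])
    for (p_lo in levels) {
      qs <- apply(curves, 2L, stats::quantile, probs = c(p_lo, 1 - p_lo),
                  names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        mode = mode, param = "joint",
        band = sprintf("Q%g-%g", 100 * p_lo, 100 * (1 - p_lo)),
        level = p_lo, h_i = grid, lower = qs[1L, ], upper = qs[2L, ],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  structure(res, m_curve = m_curve, d = d, h = h,
            class = c("taper_envelope", "data.frame"))
}

#' @export
plot.taper_envelope <- function(x, ...) {
  params <- unique(x$param)
  op <- graphics::par(mfrow = c(1, length(params)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  grid <- unique(x$h_i)
  m <- attr(x, "m_curve")
  for (pr in params) {
    sub <- x[x$param == pr, ]
    graphics::plot(NA, xlim = range(grid), ylim = c(0, max(sub$upper)),
                   xlab = "section height (m)", ylab = "diameter (cm)",
                   main = pr, ...)
    shades <- grDevices::grey(seq(0.85, 0.55, length.out = length(unique(sub$level))))
    lv <- sort(unique(sub$level))
    for (k in seq_along(lv)) {
      b <- sub[sub$level == lv[k], ]
      graphics::polygon(c(b$h_i, rev(b$h_i)), c(b$lower, rev(b$upper)),
                        col = shades[k], border = NA)
    }
    graphics::lines(grid, m, lwd = 2)
  }
  invisible(x)
}
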