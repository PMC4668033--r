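# Evaluation statistics and the M / PA / SS response surface.

#' Root mean square error with a parameter penalty
#'
#' `sqrt(sum((obs - pred)^2) / (n - p))`.
#'
#' @param obs,pred observed and predicted values of equal length.
#' @param p number of parameters charged to the denominator (default 0; the
#'   fixed-parameter count in the model-evaluation tables).
#' @return the RMSE.
#' @export
taper_rmse <- function(obs, pred, p = 0) {
  if (length(obs) != length(pred)) stop("'obs' and 'pred' differ in length")
  n <- length(obs)
  if (n <= p) stop("need n > p observations (n = ", n, ", p = ", p, ")")
  sqrt(sum((obs - pred)^2) / (n - p))
}

#' Percentage mean prediction error
#'
#' `100 * mean(obs - pred) / mean(obs)`.
#'
#' @inheritParams taper_rmse
#' @return the mean prediction error as a percentage of the observed mean.
#' @export
mpe_pct <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("'obs' and 'pred' differ in length")
  ybar <- mean(obs)
  if (abs(ybar) < .Machine$double.eps^0.5)
    stop("mean of observed values is zero; percentage error undefined")
  100 * mean(obs - pred) / ybar
}

#' Population-averaged (PA) taper predictions
#'
#' Monte-Carlo average of the subject-specific prediction over the
#' random-effects distribution: effects are drawn once from
#' `N(0, D_plot + D_tree)` (a new tree in a new plot) and shared across all
#' evaluation points, then the mean prediction is returned per observation.
#'
#' @param model a mixed-effects `taper_fit`.
#' @param data rows at which to predict (defaults to the fitting data).
#' @param n_draws Monte-Carlo draws (default 2000).
#' @param seed RNG seed for the draws.
#' @return a vector of PA diameter predictions (cm).
#' @export
pa_response <- function(model, data = NULL, n_draws = 2000L, seed = 1L) {
  stopifnot(inherits(model, "taper_fit"))
  if (is.null(model$varcomp)) stop("PA response needs a mixed-effects fit")
  if (is.null(data)) data <- model$data
  draws <- .pa_draws(model$varcomp, n_draws, seed)
  acc <- numeric(nrow(data))
  for (s in seq_len(nrow(draws))) {
    acc <- acc + kozak_taper(data$d, data$h, data$h_i, model$params,
                             effects = draws[s, ])
  }
  acc / nrow(draws)
}

.pa_draws <- function(varcomp, n_draws, seed) {
  D <- varcomp$D_plot + varcomp$D_tree
  draws <- with_seed(seed, .rmvnorm(n_draws, D))
  colnames(draws) <- varcomp$random
  draws
}

# PA volume: the random-effects average and the height integral commute, so
# integrate the pointwise MC average of pi (f/200)^2.
.pa_volume <- function(model, d, h, draws, lower, upper) {
  f <- function(t) {
    acc <- numeric(length(t))
    for (s in seq_len(nrow(draws))) {
      di <- kozak_taper(d, h, t, model$params, effects = draws[s, ])
      acc <- acc + di^2
    }
    pi * (acc / nrow(draws)) / 200^2
  }
  stats::integrate(f, lower, upper, abs.tol = 1e-8, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

#' Evaluate model responses against observed data
#'
#' Computes RMSE and percentage mean prediction error for section diameters
#' and per-tree stem volumes under the requested response types: `"M"`
#' (fixed parameters only), `"PA"` (Monte-Carlo population average),
#' `"SS-plot"` and `"SS-tree"` (subject-specific, using the EBLUPs stored at
#' fitting; the subjects must therefore belong to the fitting data).
#' Predicted volumes integrate over the same height interval as the observed
#' volume of each tree (first measured section to the tip).
#'
#' @param model a `taper_fit`.
#' @param data a `taper_data` (defaults to the fitting data).
#' @param responses subset of `c("M", "PA", "SS-plot", "SS-tree")`.
#' @param n_draws,seed Monte-Carlo settings for the PA response.
#' @param p denominator penalty for [taper_rmse()]; defaults to the
#'   fixed-parameter count.
#' @return a data frame with one row per response x variable cell.
#' @export
evaluate_taper <- function(model, data = NULL,
                           responses = c("M", "PA", "SS-plot", "SS-tree"),
                           n_draws = 2000L, seed = 1L, p = NULL) {
  stopifnot(inherits(model, "taper_fit"))
  if (is.null(data)) data <- model$data
  if (is.null(p)) p <- model$n_fixed
  responses <- match.arg(responses, c("M", "PA", "SS-plot", "SS-tree"),
                         several.ok = TRUE)
  if (is.null(model$varcomp))
    responses <- intersect(responses, "M")
  key <- paste(data$plot, data$tree, sep = "::")
  idx <- split(seq_len(nrow(data)), key)
  v_obs <- observed_volume(data)
  v_key <- paste(v_obs$plot, v_obs$tree, sep = "::")
  v_obs <- v_obs[match(names(idx), v_key), ]
  draws <- if ("PA" %in% responses) .pa_draws(model$varcomp, n_draws, seed)

  level_of <- c("M" = "mean", "SS-plot" = "plot", "SS-tree" = "tree")
  out <- list()
  for (resp in responses) {
    if (resp == "PA") {
      di_pred <- pa_response(model, data, n_draws = n_draws, seed = seed)
      v_pred <- vapply(idx, function(i) {
        .pa_volume(model, data$d[i[1L]], data$h[i[1L]], draws,
                   lower = data$h_i[i[1L]], upper = data$h[i[1L]])
      }, 1)
    } else {
      lev <- level_of[[resp]]
      di_pred <- predict(model, data, type = "diameter", level = lev)
      eff <- .level_effects(model, data, lev)
      v_pred <- vapply(seq_along(idx), function(t) {
        i <- idx[[t]]
        e <- if (is.null(eff)) NULL else eff[i[1L], ]
        stem_volume(model$params, data$d[i[1L]], data$h[i[1L]],
                    lower = data$h_i[i[1L]], upper = data$h[i[1L]],
                    effects = e)
      }, 1)
    }
    out[[length(out) + 1L]] <- data.frame(
      response = resp, variable = "d_i",
      rmse = taper_rmse(data$d_i, di_pred, p = p),
      mpe_pct = mpe_pct(data$d_i, di_pred),
      n = nrow(data), p = p, stringsAsFactors = FALSE)
    p_v <- if (length(v_pred) > p) p else 0  # small sets go unpenalized
    out[[length(out) + 1L]] <- data.frame(
      response = resp, variable = "v",
      rmse = taper_rmse(v_obs$v, v_pred, p = p_v),
      mpe_pct = mpe_pct(v_obs$v, v_pred),
      n = length(v_pred), p = p_v, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
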