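# Iterative multilevel EBLUP calibration for new subjects.

#' Calibrate plot- and tree-level random effects for new subjects
#'
#' Predicts the random effects of a new plot and its trees from one or more
#' extra diameter measurements, by iterating the multilevel EBLUP update
#' \deqn{\hat b = \hat D Z_i' (Z_i \hat D Z_i' + \hat R_i)^{-1}
#'       [y_i - f(x_i, \hat\beta, \hat b) + Z_i \hat b]}
#' from `b = 0` until the largest absolute effect update falls below `tol`.
#' By default the derivative matrix `Z` (and the residual) is re-evaluated at
#' the current effects each pass, consistent with FOCE; `update_z = FALSE`
#' holds the first linearization instead.
#'
#' @param model a mixed-effects `taper_fit`.
#' @param newdata calibration observations (`plot`, `tree`, `d`, `h`, `h_i`,
#'   `d_i`) for the trees of a single plot.
#' @param tol convergence tolerance on the maximum absolute effect update.
#' @param maxit iteration cap.
#' @param update_z re-linearize at the current effects each iteration.
#' @return an object of class `taper_calibration`: `plot_effects` (named
#'   vector), `tree_effects` (matrix, one row per calibrated tree),
#'   `iterations`, `converged`, `max_abs_update`.
#' @export
calibrate <- function(model, newdata, tol = 1e-8, maxit = 100L,
                      update_z = TRUE) {
  stopifnot(inherits(model, "taper_fit"))
  if (is.null(model$varcomp))
    stop("calibration needs a mixed-effects fit (method = \"FOCE\")")
  newdata <- if (inherits(newdata, "taper_data")) newdata else taper_data(newdata)
  if (length(unique(newdata$plot)) != 1L)
    stop("calibration observations must belong to a single plot")
  ps <- .plot_structure(newdata)[[1L]]
  vc <- model$varcomp
  nr <- length(vc$random)
  J <- length(ps$trees)
  q <- nr * (1L + J)
  b <- numeric(q)
  held <- NULL
  converged <- FALSE
  upd <- Inf
  for (it in seq_len(maxit)) {
    if (is.null(held) || update_z) {
      sys <- .assemble_system(model$params, vc, ps, b)
      if (!update_z) held <- sys
    } else {
      # hold Z and R; refresh only the residual at the current effects
      sys <- held
      fresh <- .assemble_system(model$params, vc, ps, b)
      sys$resid <- fresh$resid
    }
    DZ <- sys$D %*% t(sys$Z)
    V <- sys$Z %*% DZ + sys$R
    rhs <- sys$resid + drop(sys$Z %*% b)
    b_new <- drop(DZ %*% solve(V, rhs))
    upd <- max(abs(b_new - b))
    b <- b_new
    if (upd < tol) { converged <- TRUE; break }
  }
  tree_ids <- vapply(ps$trees, function(t) t$tree, "")
  tree_effects <- matrix(b[-seq_len(nr)], nrow = J, byrow = TRUE,
                         dimnames = list(tree_ids, vc$random))
  tree_info <- data.frame(
    tree = tree_ids,
    d = vapply(ps$trees, function(t) t$d, 1),
    h = vapply(ps$trees, function(t) t$h, 1),
    stringsAsFactors = FALSE)
  structure(list(plot = ps$plot,
                 plot_effects = stats::setNames(b[seq_len(nr)], vc$random),
                 tree_effects = tree_effects,
                 trees = tree_info,
                 iterations = it, converged = converged, max_abs_update = upd,
                 model = model),
            class = "taper_calibration")
}

#' @export
print.taper_calibration <- function(x, ...) {
  cat("Taper calibration for plot ", x$plot, " (", nrow(x$tree_effects),
      " tree(s); ", x$iterations, " iteration(s); ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("Plot-level effects:\n"); print(signif(x$plot_effects, 4))
  cat("Tree-level effects:\n"); print(signif(x$tree_effects, 4))
  invisible(x)
}

#' Subject-specific predictions from a calibration
#'
#' @param object a `taper_calibration`.
#' @param tree tree identifier within the calibrated plot (omit for
#'   plot-level localization of an arbitrary tree via `d` and `h`).
#' @param h_i section heights (m) at which to predict.
#' @param level `"tree"` adds plot- plus tree-level effects, `"plot"` only
#'   the plot-level effects.
#' @param type `"diameter"` or `"volume"`.
#' @param d,h DBH and total height; defaults taken from the calibration
#'   observations of `tree`.
#' @param lower,upper integration bounds for `type = "volume"`.
#' @param ... unused.
#' @return predicted diameters (cm) or a single volume (m^3).
#' @export
predict.taper_calibration <- function(object, tree = NULL, h_i = NULL,
                                      level = c("tree", "plot"),
                                      type = c("diameter", "volume"),
                                      d = NULL, h = NULL,
                                      lower = 0, upper = NULL, ...) {
  level <- match.arg(level)
  type <- match.arg(type)
  eff <- object$plot_effects
  if (level == "tree") {
    if (is.null(tree)) stop("tree-level prediction needs a 'tree' id")
    i <- match(tree, rownames(object$tree_effects))
    if (is.na(i)) stop("unknown tree id: ", tree)
    eff <- eff + object$tree_effects[i, ]
  }
  if (!is.null(tree)) {
    i <- match(tree, object$trees$tree)
    if (is.na(i)) stop("unknown tree id: ", tree)
    if (is.null(d)) d <- object$trees$d[i]
    if (is.null(h)) h <- object$trees$h[i]
  }
  if (is.null(d) || is.null(h)) stop("supply 'd' and 'h' (or a calibrated 'tree')")
  params <- object$model$params
  if (type == "diameter") {
    if (is.null(h_i)) stop("supply section heights 'h_i'")
    kozak_taper(d, h, h_i, params, effects = eff)
  } else {
    stem_volume(params, d, h, lower = lower,
                upper = if (is.null(upper)) h else upper, effects = eff)
  }
}

#' Calibration-height sweep over an evaluation dataset
#'
#' For every tree and every measured section, calibrates the model on that
#' single section (treating the tree as a new plot with one tree), predicts
#' all remaining sections and the total stem volume, and pools the errors
#' into relative-height classes of the calibrating section.  Mean-response
#' and plot-level predictions are kept alongside the tree-level ones so the
#' response orderings can be compared.
#'
#' @param model a mixed-effects `taper_fit`.
#' @param data evaluation `taper_data`; every tree needs at least 2 sections.
#' @param breaks relative-height class edges (default width-0.1 bins).
#' @return an object of class `taper_sweep`: `records` (one row per scored
#'   prediction), `by_class` (per-class RMSE and mean prediction error for
#'   diameters and volumes; empty classes have `n = 0` and `NA` statistics)
#'   and `overall` (aggregate RMSE per response level).
#' @export
calibration_sweep <- function(model, data, breaks = seq(0, 1, 0.1)) {
  stopifnot(inherits(model, "taper_fit"))
  data <- if (inherits(data, "taper_data")) data else taper_data(data)
  key <- paste(data$plot, data$tree, sep = "::")
  idx <- split(seq_len(nrow(data)), key)
  recs <- vector("list", length(idx))
  for (t in seq_along(idx)) {
    i <- idx[[t]]
    if (length(i) < 2L)
      stop("tree ", names(idx)[t], " has fewer than 2 sections")
    tr <- data[i, , drop = FALSE]
    d <- tr$d[1L]; h <- tr$h[1L]
    v_obs <- .frustum_volume(tr$h_i, tr$d_i, h)
    v_lower <- tr$h_i[1L]
    v_m <- stem_volume(model$params, d, h, lower = v_lower, upper = h)
    out <- vector("list", nrow(tr))
    for (k in seq_len(nrow(tr))) {
      calib <- calibrate(model, taper_data(tr[k, , drop = FALSE],
                                           provenance = "calibration"))
      eff_tree <- calib$plot_effects + calib$tree_effects[1L, ]
      eff_plot <- calib$plot_effects
      other <- setdiff(seq_len(nrow(tr)), k)
      di_ss <- kozak_taper(d, h, tr$h_i[other], model$params, effects = eff_tree)
      di_pl <- kozak_taper(d, h, tr$h_i[other], model$params, effects = eff_plot)
      di_m <- kozak_taper(d, h, tr$h_i[other], model$params)
      v_ss <- stem_volume(model$params, d, h, lower = v_lower, upper = h,
                          effects = eff_tree)
      v_pl <- stem_volume(model$params, d, h, lower = v_lower, upper = h,
                          effects = eff_plot)
      out[[k]] <- data.frame(
        plot = tr$plot[1L], tree = tr$tree[1L], d = d, h = h,
        calib_h = tr$h_i[k], calib_rel = tr$h_i[k] / h,
        variable = c(rep("d_i", length(other)), "v"),
        pred_rel = c(tr$h_i[other] / h, NA),
        obs = c(tr$d_i[other], v_obs),
        pred_ss = c(di_ss, v_ss), pred_plot = c(di_pl, v_pl),
        pred_m = c(di_m, v_m),
        stringsAsFactors = FALSE)
    }
    recs[[t]] <- do.call(rbind, out)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  p <- model$n_fixed
  by_class <- .sweep_classes(records, breaks, p)
  overall <- do.call(rbind, lapply(c("d_i", "v"), function(v) {
    sub <- records[records$variable == v, ]
    p_use <- if (nrow(sub) > p) p else 0
    data.frame(variable = v,
               rmse_m = taper_rmse(sub$obs, sub$pred_m, p = p_use),
               rmse_plot = taper_rmse(sub$obs, sub$pred_plot, p = p_use),
               rmse_tree = taper_rmse(sub$obs, sub$pred_ss, p = p_use),
               stringsAsFactors = FALSE)
  }))
  structure(list(records = records, by_class = by_class, overall = overall,
                 breaks = breaks, p = p),
            class = "taper_sweep")
}

.sweep_classes <- function(records, breaks, p) {
  bins <- cut(records$calib_rel, breaks, include.lowest = TRUE)
  n_tot <- tapply(rep(1, nrow(records)), bins, sum)
  out <- list()
  for (v in c("d_i", "v")) {
    sub <- records$variable == v
    for (lev in levels(bins)) {
      sel <- sub & !is.na(bins) & bins == lev
      n <- sum(sel)
      # parameter count apportioned by cell share; cells smaller than their
      # share are reported unpenalized
      p_g <- if (n > 0) p * n / sum(sub) else 0
      if (p_g >= n) p_g <- 0
      out[[length(out) + 1L]] <- data.frame(
        class = lev,
        mid = mean(as.numeric(strsplit(gsub("[^0-9.,]", "", lev), ",")[[1L]])),
        variable = v, n = n,
        rmse = if (n > 0) taper_rmse(records$obs[sel], records$pred_ss[sel],
                                     p = p_g) else NA_real_,
        mpe_pct = if (n > 0) mpe_pct(records$obs[sel], records$pred_ss[sel])
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.taper_sweep <- function(x, ...) {
  cat("Calibration-height sweep (", nrow(x$records), " scored predictions)\n",
      sep = "")
  cat("Aggregate RMSE by response level:\n")
  print(x$overall, row.names = FALSE, digits = 4)
  cat("\nPer calibration relative-height class (tree-level SS):\n")
  print(x$by_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Disaggregate sweep errors
#'
#' Re-bins the per-prediction errors of a [calibration_sweep()] by
#' calibration relative-height class, total tree height class, prediction
#' relative-height class, or by the calibration x prediction cross table.
#'
#' @param sweep a `taper_sweep`.
#' @param by `"calibration"`, `"total_height"`, `"prediction"`, or
#'   `c("calibration", "prediction")`.
#' @param breaks bin edges (defaults: the sweep's relative-height breaks, or
#'   3-m height classes for `"total_height"`).
#' @param variable `"d_i"` or `"v"`.
#' @return a data frame with one row per (non-empty or empty) cell: grouping
#'   labels, `n`, `rmse`, `mpe_pct`; empty cells carry `NA` statistics.
#' @export
disaggregate <- function(sweep, by = "calibration", breaks = NULL,
                         variable = "d_i") {
  stopifnot(inherits(sweep, "taper_sweep"))
  rec <- sweep$records[sweep$records$variable == variable, , drop = FALSE]
  p <- sweep$p
  getter <- list(calibration = function(r) r$calib_rel,
                 total_height = function(r) r$h,
                 prediction = function(r) r$pred_rel)
  bad <- setdiff(by, names(getter))
  if (length(bad)) stop("unknown grouping: ", paste(bad, collapse = ", "))
  brk <- function(dim) {
    if (!is.null(breaks)) return(breaks)
    if (dim == "total_height") seq(floor(min(rec$h)), ceiling(max(rec$h)) + 3, 3)
    else sweep$breaks
  }
  bins <- lapply(by, function(dim) cut(getter[[dim]](rec), brk(dim),
                                       include.lowest = TRUE))
  grid <- expand.grid(lapply(bins, levels), stringsAsFactors = FALSE)
  names(grid) <- by
  n_var <- nrow(rec)
  out <- grid
  out$n <- 0L; out$rmse <- NA_real_; out$mpe_pct <- NA_real_
  for (r in seq_len(nrow(grid))) {
    sel <- Reduce(`&`, lapply(seq_along(by), function(k)
      !is.na(bins[[k]]) & bins[[k]] == grid[r, k]))
    n <- sum(sel)
    out$n[r] <- n
    if (n > 0) {
      p_g <- p * n / n_var
      if (p_g >= n) p_g <- 0
      out$rmse[r] <- taper_rmse(rec$obs[sel], rec$pred_ss[sel], p = p_g)
      out$mpe_pct[r] <- mpe_pct(rec$obs[sel], rec$pred_ss[sel])
    }
  }
  out
}
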