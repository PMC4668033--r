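#' @keywords internal
"_PACKAGE"

# Canonical parameter order of the variable-exponent taper equation.
.kozak_names <- c("a0", "a1", "a2", "b1", "b2", "b3", "b4", "b5", "b6")

#' Default parameter vector
#'
#' Returns a full, named coefficient vector in canonical order
#' (`a0, a1, a2, b1, ..., b6`), filling unspecified entries with zero.
#'
#' @param ... named coefficient values.
#' @return named numeric vector of length 9.
#' @export
kozak_params <- function(...) {
  p <- stats::setNames(numeric(9L), .kozak_names)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .kozak_names)
    if (length(bad)) stop("unknown taper parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p
}

.full_params <- function(params) {
  if (is.null(names(params))) {
    if (length(params) != 9L) stop("unnamed 'params' must have length 9")
    names(params) <- .kozak_names
    return(params)
  }
  out <- stats::setNames(numeric(9L), .kozak_names)
  bad <- setdiff(names(params), .kozak_names)
  if (length(bad)) stop("unknown taper parameter(s): ", paste(bad, collapse = ", "))
  out[names(params)] <- params
  out
}

#' Relative height terms of the taper equation
#'
#' Computes the relative height `q = h_i/h`, the shape term `w = 1 - q^(1/3)`
#' and the normalized term `x = (1 - q^(1/3)) / (1 - (1.3/h)^(1/3))`, which
#' equals 1 exactly at breast height (`h_i = 1.3` m) and 0 at the tip.
#'
#' @param h_i section height(s) above ground (m).
#' @param h total tree height (m), `h > 1.3`.
#' @return a list with numeric components `q`, `w`, `x`.
#' @export
kozak_terms <- function(h_i, h) {
  if (any(h <= 1.3)) stop("total height 'h' must exceed breast height (1.3 m)")
  if (any(h_i < 0) || any(h_i > h + 1e-9)) stop("'h_i' must lie in [0, h]")
  q <- h_i / h
  w <- 1 - q^(1/3)
  x <- w / (1 - (1.3 / h)^(1/3))
  list(q = q, w = w, x = x)
}

# Row-wise evaluation with a full n x 9 coefficient matrix.  Used by both the
# public predictor and the finite-difference Jacobian, so it must stay cheap.
.kozak_eval <- function(d, h, h_i, theta) {
  q <- h_i / h
  w <- 1 - q^(1/3)
  x <- w / (1 - (1.3 / h)^(1/3))
  B <- theta[, 4L] * q^4 + theta[, 5L] * exp(-d / h) + theta[, 6L] * x^0.1 +
    theta[, 7L] / d + theta[, 8L] * h^w + theta[, 9L] * x
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    out[pos] <- theta[pos, 1L] * d[pos]^theta[pos, 2L] * h[pos]^theta[pos, 3L] *
      exp(B[pos] * log(x[pos]))
  }
  if (any(!pos) && any(B[!pos] <= 0)) {
    warning("tip singularity: x = 0 with non-positive exponent; diameter set to 0")
  }
  out
}

# Expand params (+ optional effects) into the n x 9 matrix .kozak_eval wants.
.theta_matrix <- function(params, effects, n) {
  params <- .full_params(params)
  theta <- matrix(params, nrow = n, ncol = 9L, byrow = TRUE,
                  dimnames = list(NULL, .kozak_names))
  if (!is.null(effects)) {
    if (is.matrix(effects)) {
      if (nrow(effects) != n) stop("effects matrix must have one row per observation")
      cols <- colnames(effects)
      if (is.null(cols) || !all(cols %in% .kozak_names))
        stop("effects columns must be named after taper parameters")
      theta[, cols] <- theta[, cols, drop = FALSE] + effects
    } else {
      cols <- names(effects)
      if (is.null(cols) || !all(cols %in% .kozak_names))
        stop("effects must be named after taper parameters")
      theta[, cols] <- sweep(theta[, cols, drop = FALSE], 2L, effects, "+")
    }
  }
  theta
}

#' Predict stem diameter from the variable-exponent taper equation
#'
#' Evaluates the Kozak (2004) model
#' \deqn{d_i = a_0 d^{a_1} h^{a_2} x^{B}, \quad
#'   B = b_1 q^4 + b_2 e^{-d/h} + b_3 x^{0.1} + b_4/d + b_5 h^w + b_6 x}
#' with \eqn{q = h_i/h}, \eqn{w = 1-q^{1/3}} and
#' \eqn{x = (1-q^{1/3})/(1-(1.3/h)^{1/3})}.  By convention the predicted
#' diameter is exactly 0 at the tip (`h_i = h`, where `x = 0`).
#'
#' @param d diameter at breast height (cm), recycled against `h_i`.
#' @param h total tree height (m), recycled against `h_i`.
#' @param h_i section height(s) (m).
#' @param params named coefficient vector (see [kozak_params()]).
#' @param effects optional random-effect offsets added to the coefficients:
#'   a named vector (applied to every observation) or an n x k matrix with
#'   parameter-named columns (one row per observation).
#' @return predicted over-bark diameter(s) (cm).
#' @examples
#' p <- taper_coefs("mm3")$params
#' kozak_taper(24, 14, c(0.5, 1.3, 7, 14), p)
#' @export
kozak_taper <- function(d, h, h_i, params, effects = NULL) {
  n <- max(length(d), length(h), length(h_i))
  d <- rep_len(d, n); h <- rep_len(h, n); h_i <- rep_len(h_i, n)
  if (any(d <= 0)) stop("'d' must be positive")
  kozak_terms(h_i, h)  # domain checks
  .kozak_eval(d, h, h_i, .theta_matrix(params, effects, n))
}

#' Partial derivatives of the taper prediction
#'
#' Central finite differences of [kozak_taper()] with respect to selected
#' coefficients, with step `1e-6 * max(1, |theta|)`.  Because random effects
#' enter additively in the coefficient vector, these columns are also the
#' entries of the random-effects design matrix Z used in linearization and
#' calibration.
#'
#' @inheritParams kozak_taper
#' @param wrt character vector of coefficient names to differentiate against.
#' @return an n x `length(wrt)` matrix of derivatives.
#' @export
kozak_gradient <- function(d, h, h_i, params, effects = NULL, wrt = .kozak_names) {
  bad <- setdiff(wrt, .kozak_names)
  if (length(bad)) stop("cannot differentiate with respect to: ", paste(bad, collapse = ", "))
  n <- max(length(d), length(h), length(h_i))
  d <- rep_len(d, n); h <- rep_len(h, n); h_i <- rep_len(h_i, n)
  theta <- .theta_matrix(params, effects, n)
  G <- matrix(0, n, length(wrt), dimnames = list(NULL, wrt))
  for (k in seq_along(wrt)) {
    j <- match(wrt[k], .kozak_names)
    step <- 1e-6 * pmax(1, abs(theta[, j]))
    tp <- theta; tp[, j] <- tp[, j] + step
    tm <- theta; tm[, j] <- tm[, j] - step
    G[, k] <- (.kozak_eval(d, h, h_i, tp) - .kozak_eval(d, h, h_i, tm)) / (2 * step)
  }
  G
}

#' Stem volume by numerical integration
#'
#' Integrates \eqn{\pi (d_i(t)/200)^2} over a height interval with adaptive
#' quadrature ([stats::integrate()]), returning volume in cubic metres.
#'
#' @inheritParams kozak_taper
#' @param lower,upper integration bounds (m) within `[0, h]`.
#' @param effects optional named vector of random-effect offsets (one tree).
#' @param abs.tol absolute quadrature tolerance (m^3).
#' @return volume (m^3).
#' @export
stem_volume <- function(params, d, h, lower = 0, upper = h, effects = NULL,
                        abs.tol = 1e-8) {
  stopifnot(length(d) == 1L, length(h) == 1L)
  if (lower < 0 || upper > h + 1e-9 || lower >= upper)
    stop("integration bounds must satisfy 0 <= lower < upper <= h")
  f <- function(t) pi * (kozak_taper(d, h, t, params, effects) / 200)^2
  stats::integrate(f, lower, upper, abs.tol = abs.tol, rel.tol = abs.tol,
                   subdivisions = 500L)$value
}

#' Merchantable height to a top diameter limit
#'
#' Finds the largest height at which the predicted stem diameter equals a
#' given top diameter, by scanning the profile downward from the tip to
#' bracket the upper (monotone decreasing) crossing and refining it with
#' [stats::uniroot()].  The taper equation has no closed-form inverse.
#'
#' @inheritParams stem_volume
#' @param top_diameter over-bark top diameter limit (cm), `> 0`.
#' @return merchantable height (m), or `NA_real_` when the limit exceeds the
#'   predicted profile everywhere above breast height.
#' @export
merchantable_height <- function(params, d, h, top_diameter, effects = NULL) {
  stopifnot(length(d) == 1L, length(h) == 1L, top_diameter > 0)
  hs <- seq(h, 1.3, length.out = 512L)
  di <- kozak_taper(d, h, hs, params, effects)
  idx <- which(di >= top_diameter)[1L]
  if (is.na(idx)) return(NA_real_)  # top diameter above the whole profile
  if (idx == 1L) return(h)
  root <- stats::uniroot(
    function(t) kozak_taper(d, h, t, params, effects) - top_diameter,
    lower = hs[idx], upper = hs[idx - 1L], tol = 1e-10)$root
  root
}
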