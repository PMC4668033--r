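# Published coefficient sets and their flat key-value serialization.

#' Packaged coefficient sets
#'
#' Published coefficient sets for the maritime pine taper equation fitted to
#' the full 420-tree Asturias dataset: `"fmols"` (fixed-effects nonlinear OLS)
#' and `"mm3"` (two-level mixed-effects model with random effects in `a1` and
#' `b3` at plot and tree level and a power-of-DBH variance function, REML).
#'
#' @param set `"fmols"` or `"mm3"`.
#' @return a list with components `params` (named length-9 vector), `random`
#'   (character vector, possibly empty), `varcomp` (see [taper_varcomp()], or
#'   `NULL` for a fixed-effects set), `sigma2` and `description`.
#' @export
taper_coefs <- function(set = c("fmols", "mm3")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0("coefs-", set, ".json"),
                      package = "pinetaper", mustWork = TRUE)
  read_taper_coefs(path)
}

#' Read or write a coefficient set as flat key-value JSON
#'
#' Coefficient files are flat JSON objects holding the nine fixed
#' coefficients, and optionally the random-effect specification (`random`),
#' covariance entries (`D_plot.<p>.<q>`, `D_tree.<p>.<q>`), residual variance
#' (`sigma2`), variance-power exponent (`delta`) and CAR(1) coefficient
#' (`phi`).
#'
#' @param path file path.
#' @return `read_taper_coefs()` returns the same structure as [taper_coefs()].
#' @export
read_taper_coefs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- kozak_params()
  for (nm in intersect(names(raw), .kozak_names)) params[nm] <- raw[[nm]]
  random <- as.character(raw$random %||% character())
  varcomp <- NULL
  if (length(random)) {
    D_plot <- .cov_from_flat(raw, "D_plot", random)
    D_tree <- .cov_from_flat(raw, "D_tree", random)
    varcomp <- taper_varcomp(random = random, D_plot = D_plot, D_tree = D_tree,
                             sigma2 = raw$sigma2, delta = raw$delta %||% NULL,
                             phi = raw$phi %||% NULL)
  }
  list(params = params, random = random, varcomp = varcomp,
       sigma2 = raw$sigma2 %||% NULL,
       description = raw$description %||% basename(path))
}

#' @rdname read_taper_coefs
#' @param coefs a list like the one returned by [taper_coefs()], or a fitted
#'   model from [taper_fit()].
#' @export
write_taper_coefs <- function(coefs, path) {
  if (inherits(coefs, "taper_fit")) {
    coefs <- list(params = coefs$params, random = coefs$random,
                  varcomp = coefs$varcomp, sigma2 = coefs$varcomp$sigma2,
                  description = paste("pinetaper", coefs$method, "fit"))
  }
  out <- list(description = coefs$description %||% "pinetaper coefficient set")
  p <- .full_params(coefs$params)
  for (nm in .kozak_names) out[[nm]] <- unname(p[nm])
  vc <- coefs$varcomp
  if (!is.null(vc)) {
    out$random <- as.list(vc$random)
    for (lv in c("D_plot", "D_tree")) {
      D <- vc[[lv]]
      for (i in seq_along(vc$random)) for (j in i:length(vc$random)) {
        key <- paste(lv, vc$random[i], vc$random[j], sep = ".")
        out[[key]] <- unname(D[i, j])
      }
    }
    out$sigma2 <- vc$sigma2
    if (!is.null(vc$delta)) out$delta <- vc$delta
    if (!is.null(vc$phi)) out$phi <- vc$phi
  } else if (!is.null(coefs$sigma2)) {
    out$sigma2 <- coefs$sigma2
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.cov_from_flat <- function(raw, prefix, random) {
  k <- length(random)
  D <- matrix(0, k, k, dimnames = list(random, random))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    key1 <- paste(prefix, random[i], random[j], sep = ".")
    key2 <- paste(prefix, random[j], random[i], sep = ".")
    val <- raw[[key1]] %||% raw[[key2]]
    if (is.null(val)) stop("missing covariance entry ", key1, " in coefficient file")
    D[i, j] <- val
  }
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a
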