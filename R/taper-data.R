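# Hierarchical stem-analysis data: plots > trees > sections.

#' Construct a taper dataset
#'
#' A taper dataset is a data frame with one row per measured stem section and
#' standardized columns `plot`, `tree` (identifiers), `d` (DBH, cm), `h`
#' (total height, m), `h_i` (section height, m) and `d_i` (over-bark section
#' diameter, cm).  Rows are sorted by plot, tree and section height on
#' construction and the hierarchy invariants are validated.
#'
#' @param df a data frame holding (at least) the six columns above.
#' @param provenance free-text label describing the data origin.
#' @return an object of class `taper_data` (a validated, sorted data frame).
#' @export
taper_data <- function(df, provenance = "unspecified") {
  req <- c("plot", "tree", "d", "h", "h_i", "d_i")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$plot <- as.character(df$plot)
  df$tree <- as.character(df$tree)
  for (v in c("d", "h", "h_i", "d_i")) {
    if (!is.numeric(df[[v]])) {
      suppressWarnings(num <- as.numeric(df[[v]]))
      if (anyNA(num) && !all(is.na(df[[v]]) == is.na(num)))
        stop("non-numeric value in column '", v, "' at row(s) ",
             paste(utils::head(which(is.na(num) != is.na(df[[v]])), 5L), collapse = ", "))
      df[[v]] <- num
    }
  }
  .validate_rows(df)
  ord <- order(df$plot, df$tree, df$h_i)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$plot, df$tree, sep = "\r")
  dup <- duplicated(cbind(key, df$h_i))
  if (any(dup))
    stop("duplicate section height within a tree at sorted row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "))
  # tree-level covariates must be constant within tree
  for (v in c("d", "h")) {
    if (any(tapply(df[[v]], key, function(z) max(z) - min(z)) > 0))
      stop("column '", v, "' is not constant within a tree")
  }
  structure(df, provenance = provenance,
            class = c("taper_data", "data.frame"))
}

.validate_rows <- function(df) {
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      stop("invalid data: ", what, " at row(s) ",
           paste(utils::head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) " ...", call. = FALSE)
    }
  }
  bad(!(df$d > 0), "DBH 'd' must be positive")
  bad(!(df$h > 1.3), "total height 'h' must exceed 1.3 m")
  bad(!(df$h_i >= 0), "section height 'h_i' must be non-negative")
  bad(!(df$d_i >= 0), "section diameter 'd_i' must be non-negative")
  bad(df$h_i > df$h + 1e-9, "section height 'h_i' exceeds total height 'h'")
}

#' @export
print.taper_data <- function(x, n = 10L, ...) {
  cat("Stem taper dataset (", attr(x, "provenance"), ")\n", sep = "")
  cat(sprintf("  %d plots, %d trees, %d sections\n",
              length(unique(x$plot)),
              length(unique(paste(x$plot, x$tree, sep = "\r"))), nrow(x)))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Column-name dialect for delimited taper files
#'
#' Maps the standardized column names onto the names used in a particular
#' file.  Defaults follow the common field convention `plot, tree, dbh,
#' htot, hsec, dsec`.
#'
#' @param plot,tree,dbh,htot,hsec,dsec column names in the file.
#' @return a named character vector (names are the standard columns).
#' @export
taper_dialect <- function(plot = "plot", tree = "tree", dbh = "dbh",
                          htot = "htot", hsec = "hsec", dsec = "dsec") {
  c(plot = plot, tree = tree, d = dbh, h = htot, h_i = hsec, d_i = dsec)
}

#' Read and write delimited taper data
#'
#' Reads a CSV or TSV file (delimiter autodetected from the extension:
#' `.tsv`/`.txt` are tab-delimited, everything else comma-delimited) with a
#' header row, renames columns according to `dialect`, and validates the
#' result with [taper_data()].
#'
#' @param path file path.
#' @param dialect a mapping from [taper_dialect()].
#' @return a `taper_data` object.
#' @export
read_taper_csv <- function(path, dialect = taper_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(unname(dialect), names(raw))
  if (length(miss))
    stop("column(s) ", paste(miss, collapse = ", "),
         " not found in ", path, "; adjust the dialect mapping")
  df <- raw[unname(dialect)]
  names(df) <- names(dialect)
  taper_data(df, provenance = basename(path))
}

#' @rdname read_taper_csv
#' @param data a `taper_data` object.
#' @export
write_taper_csv <- function(data, path, dialect = taper_dialect()) {
  stopifnot(inherits(data, "taper_data"))
  out <- as.data.frame(data)[names(dialect)]
  names(out) <- unname(dialect)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Observed stem volume from section measurements
#'
#' Computes per-tree over-bark stem volume by summing conical frustums over
#' consecutive section pairs and treating the top section (last measurement
#' to the tip) as a cone, with radii `d_i/200` in metres.
#'
#' @param data a `taper_data` object.
#' @return a data frame with one row per tree: `plot`, `tree`, `d`, `h`, `v`
#'   (m^3).
#' @export
observed_volume <- function(data) {
  stopifnot(inherits(data, "taper_data"))
  key <- paste(data$plot, data$tree, sep = "\r")
  idx <- split(seq_len(nrow(data)), key)
  rows <- lapply(idx, function(i) {
    tr <- data[i, , drop = FALSE]
    data.frame(plot = tr$plot[1L], tree = tr$tree[1L], d = tr$d[1L],
               h = tr$h[1L], v = .frustum_volume(tr$h_i, tr$d_i, tr$h[1L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$plot, out$tree), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.frustum_volume <- function(h_i, d_i, h) {
  if (length(h_i) < 2L)
    stop("observed volume needs at least 2 sections per tree")
  r <- d_i / 200
  L <- diff(h_i)
  frustums <- sum(pi * L / 3 * (r[-length(r)]^2 + r[-length(r)] * r[-1L] + r[-1L]^2))
  cone <- pi * (h - h_i[length(h_i)]) / 3 * r[length(r)]^2
  frustums + cone
}

#' Random fitting/evaluation split by plot
#'
#' Assigns whole plots at random to a fitting and an evaluation subset, so
#' that trees of one plot are never separated.
#'
#' @param data a `taper_data` object with at least 2 plots.
#' @param fit_fraction proportion of plots assigned to the fitting side; the
#'   fitting side receives `round(fit_fraction * n_plots)` plots.
#' @param seed integer seed making the split reproducible.
#' @return a list with `taper_data` components `fit` and `eval`.
#' @export
split_by_plot <- function(data, fit_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(data, "taper_data"))
  if (fit_fraction <= 0 || fit_fraction >= 1) stop("'fit_fraction' must be in (0, 1)")
  plots <- unique(data$plot)
  if (length(plots) < 2L) stop("need at least 2 plots to split")
  n_fit <- round(fit_fraction * length(plots))
  if (n_fit < 1L || n_fit >= length(plots))
    stop("'fit_fraction' leaves one side empty for ", length(plots), " plots")
  fit_plots <- with_seed(seed, sample(plots, n_fit))
  prov <- attr(data, "provenance")
  list(fit = taper_data(data[data$plot %in% fit_plots, , drop = FALSE],
                        provenance = paste0(prov, " [fitting]")),
       eval = taper_data(data[!data$plot %in% fit_plots, , drop = FALSE],
                         provenance = paste0(prov, " [evaluation]")))
}

# Run code with a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
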