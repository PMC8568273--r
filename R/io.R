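# Plain-text signal I/O, result serialisation and the diagnostic plots
# (multiscale curve, second-order difference plot, gridded Poincare
# census).

detect_delim <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "," else
    if (grepl("\t", line, fixed = TRUE)) "\t" else ""
}

#' Read a signal from a plain-text file
#'
#' Parses a one-column (series), two-column (pair) or rectangular
#' (matrix) numeric text file; the delimiter (comma, tab or whitespace)
#' is auto-detected from the first data line. Non-numeric cells are
#' reported with their row number; ragged matrices are rejected.
#'
#' @param path file path.
#' @param kind `"series"`, `"pair"` or `"matrix"`.
#' @return numeric vector (`series`), 2-column matrix (`pair`) or matrix
#'   (`matrix`), validated finite.
#' @export
read_signal <- function(path, kind = c("series", "pair", "matrix")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("file is empty: %s", path),
                           call. = FALSE)
  delim <- detect_delim(lines[1L])
  rows <- lapply(seq_along(lines), function(i) {
    cells <- if (delim == "") strsplit(trimws(lines[i]), "\\s+")[[1L]] else
      trimws(strsplit(lines[i], delim, fixed = TRUE)[[1L]])
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v) || any(!is.finite(v)))
      stop(sprintf("non-numeric or non-finite value at row %d of %s", i,
                   path), call. = FALSE)
    v
  })
  ncols <- vapply(rows, length, integer(1))
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged rows in %s (column counts %s)", path,
                 paste(unique(ncols), collapse = ", ")), call. = FALSE)
  mat <- do.call(rbind, rows)
  switch(kind,
    series = {
      if (ncol(mat) != 1L)
        stop(sprintf("expected 1 column for a series, found %d in %s",
                     ncol(mat), path), call. = FALSE)
      as.numeric(mat[, 1L])
    },
    pair = {
      if (ncol(mat) != 2L)
        stop(sprintf("expected 2 columns for a pair, found %d in %s",
                     ncol(mat), path), call. = FALSE)
      unname(mat)
    },
    matrix = unname(mat))
}

#' Write a signal to a plain-text file
#'
#' Inverse of [read_signal()]: writes a vector as one column or a matrix
#' as comma-separated rows, with 17 significant digits so a read
#' round-trips to within 1e-15 relative.
#'
#' @param x numeric vector or matrix.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path) {
  fmt <- function(v) format(v, digits = 17, scientific = TRUE, trim = TRUE)
  if (is.matrix(x)) {
    writeLines(apply(x, 1L, function(r) paste(fmt(r), collapse = ",")),
               path)
  } else {
    writeLines(fmt(as.numeric(x)), path)
  }
  invisible(path)
}

result_payload <- function(res, version = as.character(utils::packageVersion("entropics"))) {
  if (inherits(res, "entropy_result")) {
    list(kind = "entropy_result", estimator = res$estimator,
         primary = res$primary,
         secondary = res$secondary[!vapply(res$secondary, function(s)
           is.matrix(s) || length(s) > 64L, logical(1))],
         params = res$params, toolkit_version = version)
  } else if (inherits(res, "ms_curve")) {
    list(kind = res$kind, estimator = res$spec$name,
         scales = res$scales, values = res$values,
         complexity_index = res$complexity_index,
         graining = res$graining, params = res$spec$params,
         toolkit_version = version)
  } else if (inherits(res, "hms_tree")) {
    list(kind = res$kind, estimator = res$spec$name, depth = res$depth,
         nodes = res$nodes, layer_means = as.numeric(res$layer_means),
         params = res$spec$params, toolkit_version = version)
  } else stop("unsupported result object", call. = FALSE)
}

#' Serialise a result to JSON or CSV
#'
#' Writes an [entropy_result], multiscale curve or hierarchical tree with
#' its fully resolved parameter set and toolkit version. JSON keeps full
#' precision (17 significant digits); the CSV schema is `scale,value`
#' rows for curves and flat `key,value` rows for scalar results.
#'
#' @param res result object.
#' @param path destination file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(res, path, format = c("json", "csv")) {
  format <- match.arg(format)
  payload <- result_payload(res)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  } else {
    if (inherits(res, "ms_curve")) {
      utils::write.csv(data.frame(scale = res$scales, value = res$values),
                       path, row.names = FALSE)
    } else if (inherits(res, "hms_tree")) {
      utils::write.csv(res$nodes, path, row.names = FALSE)
    } else {
      prim <- res$primary
      nm <- if (length(prim) > 1L)
        paste0("primary_level_", seq_along(prim) - 1L) else "primary"
      utils::write.csv(data.frame(key = nm,
                                  value = format(prim, digits = 17)),
                       path, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Plot a multiscale entropy curve
#'
#' Entropy against temporal scale with one marker per scale, the standard
#' presentation of a multiscale analysis.
#'
#' @param curve an `ms_curve`.
#' @param file optional PNG path; when `NULL`, plots to the active device.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_ms_curve <- function(curve, file = NULL) {
  if (!inherits(curve, "ms_curve"))
    stop("`curve` must be an ms_curve", call. = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(curve$scales, curve$values, type = "b", pch = 19,
                 col = "steelblue", lwd = 2,
                 xlab = "Temporal scale", ylab = "Entropy",
                 main = sprintf("%s (%s)", curve$kind, curve$spec$name))
  graphics::grid()
  invisible(file)
}

#' @export
plot.ms_curve <- function(x, ...) plot_ms_curve(x)

#' Second-order difference plot
#'
#' Scatter of successive lagged differences
#' `x(t + 2 tau) - x(t + tau)` against `x(t + tau) - x(t)` with the `K`
#' angular sector boundaries used by phase entropy overlaid.
#'
#' @param x numeric series (or an [entropy_result] from [phasen()]).
#' @param tau time delay (default 1).
#' @param K number of sectors drawn (default 4).
#' @param file optional PNG path.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_sodp <- function(x, tau = 1L, K = 4L, file = NULL) {
  if (inherits(x, "entropy_result")) {
    if (x$estimator != "PhasEn")
      stop("result does not carry second-order difference coordinates",
           call. = FALSE)
    u <- x$secondary$u; y <- x$secondary$y; K <- x$params$K
  } else {
    res <- phasen(x, K = K, tau = tau)
    u <- res$secondary$u; y <- res$secondary$y
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  lim <- max(abs(c(u, y)))
  graphics::plot(u, y, pch = ".", col = "darkblue", asp = 1,
                 xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = expression(x[t + tau] - x[t]),
                 ylab = expression(x[t + 2 * tau] - x[t + tau]),
                 main = "Second-order difference plot")
  for (k in seq_len(K)) {
    a <- 2 * pi * (k - 1) / K
    graphics::segments(0, 0, 1.2 * lim * cos(a), 1.2 * lim * sin(a),
                       col = "grey50", lty = 2)
  }
  invisible(file)
}

#' Gridded Poincare plot
#'
#' Scatter of `x(t)` against `x(t + tau)` with the `m x m` grid partition
#' used by gridded distribution entropy overlaid; cell counts are shown
#' as background shading.
#'
#' @param x numeric series (or an [entropy_result] from [griden()]).
#' @param m grid partitions per axis (default 3).
#' @param tau time delay (default 1).
#' @param file optional PNG path.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_grid_census <- function(x, m = 3L, tau = 1L, file = NULL) {
  if (inherits(x, "entropy_result")) {
    if (x$estimator != "GridEn")
      stop("result does not carry a Poincare grid census", call. = FALSE)
    res <- x
  } else res <- griden(x, m = m, tau = tau)
  a <- res$secondary$a; b <- res$secondary$b
  census <- res$secondary$census
  m <- res$params$m
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  rng <- range(c(a, b))
  brk <- seq(rng[1], rng[2], length.out = m + 1L)
  graphics::image(brk, brk, census / max(1, max(census)),
                  col = grDevices::hcl.colors(16, "Blues", rev = TRUE),
                  xlab = expression(x[t]), ylab = expression(x[t + tau]),
                  main = "Poincare plot with grid census")
  graphics::points(a, b, pch = ".", col = grDevices::adjustcolor("black", 0.5))
  graphics::abline(v = brk, h = brk, col = "grey40", lty = 3)
  invisible(file)
}
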