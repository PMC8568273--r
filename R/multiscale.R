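# Multiscale engines: estimator specs (frozen parameter sets), graining
# procedures, and the classic / composite / refined-composite / refined /
# hierarchical drivers. A driver evaluates the spec'd estimator on a
# rescaled version of the series at each scale; the scalar per scale is
# the last element of the estimator's level vector.

MIN_GRAINED_LENGTH <- 10L

#' Create a multiscale estimator spec
#'
#' Freezes an estimator name and keyword parameters into an immutable spec
#' that multiscale drivers re-use verbatim at every scale. Parameters are
#' validated against the estimator's signature at construction.
#'
#' @param name estimator id from the base or cross registry.
#' @param params named list of frozen keyword parameters.
#' @return object of class `ms_spec` with fields `name`, `params`,
#'   `family` (`"base"` or `"cross"`).
#' @examples
#' make_spec("SampEn")
#' make_spec("XDistEn", list(binning = "sturges"))
#' @export
make_spec <- function(name, params = list()) {
  if (!is.character(name) || length(name) != 1L)
    stop("`name` must be a single estimator id", call. = FALSE)
  base_map <- base_registry_map()
  cross_map <- cross_registry_map()
  if (name %in% names(base_map)) {
    family <- "base"; fn <- base_map[[name]]
  } else if (name %in% names(cross_map)) {
    family <- "cross"; fn <- cross_map[[name]]
  } else {
    stop(sprintf("unknown estimator '%s'; valid names: %s", name,
                 paste(c(names(base_map), names(cross_map)), collapse = ", ")),
         call. = FALSE)
  }
  if (length(params) && (is.null(names(params)) || any(names(params) == "")))
    stop("`params` must be a fully named list", call. = FALSE)
  bad <- setdiff(names(params), names(formals(fn)))
  if (length(bad))
    stop(sprintf("invalid parameter(s) for %s: %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(name = name, params = params, family = family),
            class = "ms_spec")
}

#' @export
print.ms_spec <- function(x, ...) {
  cat(sprintf("<ms_spec: %s (%s estimator)>\n", x$name, x$family))
  if (length(x$params))
    cat("  frozen params:", paste(names(x$params), unlist(x$params),
                                  sep = "=", collapse = " "), "\n")
  invisible(x)
}

call_spec <- function(spec, x, y = NULL, extra = list()) {
  params <- utils::modifyList(spec$params, extra)
  if (spec$family == "base") {
    do.call(base_registry_map()[[spec$name]], c(list(x), params))
  } else {
    do.call(cross_registry_map()[[spec$name]], c(list(x, y), params))
  }
}

# scalar estimate used per scale: last element of the level vector
scalar_estimate <- function(res) {
  v <- res$primary
  v[length(v)]
}

# Classic multiscale convention: a free tolerance radius is computed once
# from the raw series (0.2 x SD) and frozen across scales, so entropy
# changes reflect the graining, not a rescaled tolerance. Returns the
# extra parameter list to splice into every scale's call.
frozen_radius_extra <- function(spec, x, y = NULL) {
  map <- if (spec$family == "base") base_registry_map() else
    cross_registry_map()
  takes_r <- "r" %in% names(formals(map[[spec$name]]))
  if (!takes_r || "r" %in% names(spec$params)) return(list())
  s <- stats::sd(c(x, y))
  if (!is.finite(s) || s == 0) return(list())
  list(r = 0.2 * s)
}

#' Coarse-grain a series
#'
#' Rescales a series to temporal scale `s`:
#' * `coarse` — means of non-overlapping windows of length `s` (the
#'   classic multiscale-entropy low-pass + decimation).
#' * `modified` — moving average of length `s` without decimation
#'   (length `n - s + 1`), preserving the sampling rate.
#' * `generalized` — variances (population) of non-overlapping windows,
#'   tracking volatility rather than level.
#'
#' Scale 1 is the identity for every method.
#'
#' @param x numeric series.
#' @param scale integer scale >= 1.
#' @param method graining procedure.
#' @return numeric vector (shorter than `x` for `scale > 1`).
#' @examples
#' coarse_grain(1:6, 2) # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, scale,
                         method = c("coarse", "modified", "generalized")) {
  scale <- check_positive_int(scale, "scale")
  method <- match.arg(method)
  n <- length(x)
  if (scale > n) stop("`scale` exceeds the series length", call. = FALSE)
  if (scale == 1L) return(x)
  if (method == "coarse") {
    k <- floor(n / scale)
    colMeans(matrix(x[seq_len(k * scale)], nrow = scale))
  } else if (method == "modified") {
    as.numeric(stats::filter(x, rep(1 / scale, scale),
                             sides = 1)[scale:n])
  } else {
    k <- floor(n / scale)
    w <- matrix(x[seq_len(k * scale)], nrow = scale)
    colMeans(w^2) - colMeans(w)^2
  }
}

new_ms_curve <- function(scales, values, graining, spec, kind = "MSEn",
                         extra = list()) {
  structure(c(list(scales = scales, values = values,
                   complexity_index = sum(values), graining = graining,
                   spec = spec, kind = kind), extra),
            class = "ms_curve")
}

#' @export
print.ms_curve <- function(x, ...) {
  cat(sprintf("<%s curve: %s over %d scales (%s graining)>\n", x$kind,
              x$spec$name, length(x$scales), x$graining))
  print(stats::setNames(signif(x$values, 5), paste0("s", x$scales)))
  cat("  complexity index:", signif(x$complexity_index, 6), "\n")
  invisible(x)
}

grained_or_na <- function(x, s, graining, spec) {
  g <- coarse_grain(x, s, graining)
  if (length(g) < MIN_GRAINED_LENGTH) {
    warning(sprintf(
      "scale %d leaves %d samples (< %d); value reported as missing",
      s, length(g), MIN_GRAINED_LENGTH), call. = FALSE)
    return(NULL)
  }
  g
}

eval_scale <- function(spec, g, gy = NULL, scale, extra = list()) {
  tryCatch(scalar_estimate(call_spec(spec, g, gy, extra)),
           error = function(e) stop(sprintf("scale %d: %s", scale,
                                            conditionMessage(e)),
                                    call. = FALSE))
}

#' Multiscale entropy (MSEn)
#'
#' Evaluates a base estimator spec on grained versions of the series at
#' scales `1..scales`; scale 1 is the raw series. Following the classic
#' multiscale convention, a free tolerance radius is computed once as
#' `0.2 * sd(x)` of the raw series and frozen across scales (freeze a
#' different value via the spec's `r`); the refined driver [rmsen()] is
#' the variant that re-derives it per scale. The complexity index is the
#' sum of the curve. Scales whose grained series falls below 10 samples
#' are reported as `NA` with a warning.
#'
#' @param x numeric series.
#' @param spec [make_spec()] object with a base-family estimator.
#' @param scales number of temporal scales (default 3).
#' @param graining graining method, see [coarse_grain()].
#' @return object of class `ms_curve`.
#' @examples
#' set.seed(1)
#' msen(rnorm(400), make_spec("SampEn"), scales = 3)
#' @export
msen <- function(x, spec, scales = 3L,
                 graining = c("coarse", "modified", "generalized")) {
  if (!inherits(spec, "ms_spec"))
    stop("`spec` must be an ms_spec (see make_spec()); multiscale drivers require an estimator spec",
         call. = FALSE)
  if (spec$family != "base")
    stop("msen() requires a base-family estimator spec", call. = FALSE)
  graining <- match.arg(graining)
  scales <- check_positive_int(scales, "scales")
  x <- validate_series(x)
  extra <- frozen_radius_extra(spec, x)
  vals <- rep(NA_real_, scales)
  for (s in seq_len(scales)) {
    g <- grained_or_na(x, s, graining, spec)
    if (!is.null(g)) vals[s] <- eval_scale(spec, g, scale = s,
                                           extra = extra)
  }
  new_ms_curve(seq_len(scales), vals, graining, spec, "MSEn")
}

# offset grains used by the composite drivers: window means starting at
# offset o (0-based) for o = 0..s-1
offset_grain <- function(x, s, o) {
  y <- x[(o + 1L):length(x)]
  k <- floor(length(y) / s)
  if (k < 1L) return(numeric(0))
  colMeans(matrix(y[seq_len(k * s)], nrow = s))
}

rc_supported <- c("SampEn", "FuzzEn", "XSampEn", "XFuzzEn")

rc_pool <- function(spec, grains, gy = NULL, scale, extra = list()) {
  # refined-composite pooling: match counts (or memberships) accumulated
  # across all grain offsets before the log
  resl <- lapply(seq_along(grains), function(i)
    call_spec(spec, grains[[i]], if (is.null(gy)) NULL else gy[[i]],
              extra))
  lb <- resl[[1L]]$params$log_base
  if (spec$name %in% c("SampEn", "XSampEn")) {
    A <- rowSums(vapply(resl, function(r) r$secondary$A, resl[[1]]$secondary$A))
    B <- rowSums(vapply(resl, function(r) r$secondary$B, resl[[1]]$secondary$B))
    k <- length(A)
    if (A[k] == 0 || B[k] == 0) {
      warning(sprintf("scale %d: no pooled matches; returning Inf", scale),
              call. = FALSE)
      return(Inf)
    }
    -log(A[k] / B[k]) / log(lb)
  } else {
    phi <- rowMeans(vapply(resl, function(r) r$secondary$phi,
                           resl[[1]]$secondary$phi))
    k <- length(phi)
    (log(phi[k - 1L]) - log(phi[k])) / log(lb)
  }
}

#' Composite and refined-composite multiscale entropy (cMSEn)
#'
#' At each scale `s` the coarse-graining can start at any of the `s`
#' offsets; the composite estimate is the mean of the estimator over all
#' offset grains, reducing the variance of the classic curve. The
#' refined-composite form instead pools the template match counts (or
#' fuzzy memberships) across offsets before taking the log, and is
#' available for the estimators that expose them
#' (SampEn / FuzzEn / XSampEn / XFuzzEn).
#'
#' @inheritParams msen
#' @param refined pool match counts across offsets (default `FALSE`).
#' @return `ms_curve`.
#' @export
cmsen <- function(x, spec, scales = 3L, refined = FALSE) {
  if (!inherits(spec, "ms_spec"))
    stop("`spec` must be an ms_spec (see make_spec())", call. = FALSE)
  if (spec$family != "base")
    stop("cmsen() requires a base-family estimator spec", call. = FALSE)
  if (refined && !(spec$name %in% rc_supported))
    stop(sprintf(
      "refined-composite pooling needs per-level match counts; %s does not expose them (supported: %s)",
      spec$name, paste(rc_supported, collapse = ", ")), call. = FALSE)
  scales <- check_positive_int(scales, "scales")
  x <- validate_series(x)
  extra <- frozen_radius_extra(spec, x)
  vals <- rep(NA_real_, scales)
  for (s in seq_len(scales)) {
    grains <- lapply(0:(s - 1L), function(o) offset_grain(x, s, o))
    if (any(vapply(grains, length, integer(1)) < MIN_GRAINED_LENGTH)) {
      warning(sprintf("scale %d grains below %d samples; value missing", s,
                      MIN_GRAINED_LENGTH), call. = FALSE)
      next
    }
    vals[s] <- if (refined) rc_pool(spec, grains, scale = s,
                                    extra = extra) else
      mean(vapply(grains, function(g)
        eval_scale(spec, g, scale = s, extra = extra), numeric(1)))
  }
  new_ms_curve(seq_len(scales), vals, "coarse", spec,
               if (refined) "rcMSEn" else "cMSEn")
}

# zero-phase Butterworth low-pass + decimation used by the refined driver
refined_rescale <- function(x, s) {
  if (s == 1L) return(x)
  bf <- signal::butter(6, 0.5 / s, type = "low")
  f <- signal::filtfilt(bf, x)
  if (any(!is.finite(f)))
    stop(sprintf("low-pass filter unstable at scale %d", s), call. = FALSE)
  f[seq(1L, length(f), by = s)]
}

#' Refined multiscale entropy (rMSEn)
#'
#' Replaces window averaging by a zero-phase order-6 Butterworth low-pass
#' at cutoff `0.5/s` of Nyquist followed by decimation by `s`, removing
#' the aliasing of the classic procedure. The tolerance radius (for
#' estimators that take one and whose spec leaves it free) is recomputed
#' as `0.2 * SD` of the filtered, decimated series at each scale.
#'
#' @inheritParams msen
#' @return `ms_curve`.
#' @export
rmsen <- function(x, spec, scales = 3L) {
  if (!inherits(spec, "ms_spec"))
    stop("`spec` must be an ms_spec (see make_spec())", call. = FALSE)
  if (spec$family != "base")
    stop("rmsen() requires a base-family estimator spec", call. = FALSE)
  scales <- check_positive_int(scales, "scales")
  x <- validate_series(x)
  takes_r <- "r" %in% names(formals(base_registry_map()[[spec$name]])) &&
    !("r" %in% names(spec$params))
  vals <- rep(NA_real_, scales)
  for (s in seq_len(scales)) {
    g <- refined_rescale(x, s)
    if (length(g) < MIN_GRAINED_LENGTH) {
      warning(sprintf("scale %d leaves %d samples; value missing", s,
                      length(g)), call. = FALSE)
      next
    }
    extra <- if (takes_r) list(r = 0.2 * stats::sd(g)) else list()
    vals[s] <- eval_scale(make_spec(spec$name,
                                    utils::modifyList(spec$params, extra)),
                          g, scale = s)
  }
  new_ms_curve(seq_len(scales), vals, "butterworth", spec, "rMSEn")
}

# paired averaging / differencing operators of the hierarchical
# decomposition; together they losslessly encode the parent pairs
hier_low <- function(u) {
  k <- floor(length(u) / 2)
  (u[2 * seq_len(k) - 1L] + u[2 * seq_len(k)]) / 2
}
hier_high <- function(u) {
  k <- floor(length(u) / 2)
  (u[2 * seq_len(k) - 1L] - u[2 * seq_len(k)]) / 2
}

build_hier_tree <- function(x, depth) {
  nodes <- vector("list", 2^(depth + 1L) - 1L)
  nodes[[1L]] <- x
  if (depth > 0) for (k in seq_len(2^depth - 1L)) {
    nodes[[2L * k]] <- hier_low(nodes[[k]])
    nodes[[2L * k + 1L]] <- hier_high(nodes[[k]])
  }
  nodes
}

#' Hierarchical multiscale entropy (hMSEn)
#'
#' Builds a binary tree by paired averaging (low-frequency component) and
#' paired differencing (high-frequency component); each of the
#' `2^(depth+1) - 1` node series is scored by the spec'd estimator. Node
#' `k`'s children are `2k` (low) and `2k + 1` (high), so the decomposition
#' losslessly reconstructs every parent pair.
#'
#' @inheritParams msen
#' @param depth tree depth (>= 0; depth 0 scores only the raw series).
#' @return object of class `hms_tree`: data frame of node estimates plus
#'   `layer_means` and the node series.
#' @export
hmsen <- function(x, spec, depth = 2L) {
  if (!inherits(spec, "ms_spec"))
    stop("`spec` must be an ms_spec (see make_spec())", call. = FALSE)
  if (spec$family != "base")
    stop("hmsen() requires a base-family estimator spec", call. = FALSE)
  depth <- check_positive_int(depth, "depth", min = 0L)
  x <- validate_series(x)
  if (length(x) < 2^depth * MIN_GRAINED_LENGTH)
    stop(sprintf("series too short for depth %d: need n >= %d", depth,
                 2^depth * MIN_GRAINED_LENGTH), call. = FALSE)
  nodes <- build_hier_tree(x, depth)
  extra <- frozen_radius_extra(spec, x)
  layer <- floor(log2(seq_along(nodes)))
  vals <- vapply(seq_along(nodes), function(k)
    eval_scale(spec, nodes[[k]], scale = layer[k] + 1L, extra = extra),
    numeric(1))
  df <- data.frame(node = seq_along(nodes), layer = layer,
                   type = ifelse(seq_along(nodes) == 1L, "root",
                                 ifelse(seq_along(nodes) %% 2L == 0L,
                                        "low", "high")),
                   n = vapply(nodes, length, integer(1)), value = vals)
  structure(list(nodes = df,
                 layer_means = tapply(vals, layer, mean),
                 series = nodes, spec = spec, depth = depth,
                 kind = "hMSEn"),
            class = "hms_tree")
}

#' @export
print.hms_tree <- function(x, ...) {
  cat(sprintf("<%s tree: %s, depth %d, %d nodes>\n", x$kind, x$spec$name,
              x$depth, nrow(x$nodes)))
  print(x$nodes[, c("node", "layer", "type", "n", "value")],
        row.names = FALSE)
  invisible(x)
}
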