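# Multiscale cross-entropy drivers: the four engines applied to a pair of
# series with a cross-family estimator spec. Both series are always
# grained with identical parameters and offsets.

check_cross_spec <- function(spec, fname) {
  if (!inherits(spec, "ms_spec"))
    stop("`spec` must be an ms_spec (see make_spec())", call. = FALSE)
  if (spec$family != "cross")
    stop(sprintf("%s() requires a cross-family estimator spec (got '%s', a %s estimator)",
                 fname, spec$name, spec$family), call. = FALSE)
  invisible(TRUE)
}

#' Multiscale cross-entropy (XMSEn)
#'
#' Evaluates a cross estimator spec on identically grained versions of
#' both series at scales `1..scales`. The default scale count follows the
#' univariate driver (3); the worked examples in the field typically use
#' 5-7, passed explicitly via `scales`.
#'
#' @param x,y paired numeric series.
#' @param spec [make_spec()] object with a cross-family estimator.
#' @param scales number of temporal scales (default 3).
#' @param graining graining method, see [coarse_grain()].
#' @return object of class `ms_curve`.
#' @examples
#' set.seed(1)
#' xmsen(runif(400), runif(400), make_spec("XDistEn"), scales = 3)
#' @export
xmsen <- function(x, y, spec, scales = 3L,
                  graining = c("coarse", "modified", "generalized")) {
  check_cross_spec(spec, "xmsen")
  graining <- match.arg(graining)
  scales <- check_positive_int(scales, "scales")
  p <- validate_pair(x, y)
  extra <- frozen_radius_extra(spec, p$x, p$y)
  vals <- rep(NA_real_, scales)
  for (s in seq_len(scales)) {
    gx <- grained_or_na(p$x, s, graining, spec)
    gy <- grained_or_na(p$y, s, graining, spec)
    if (!is.null(gx) && !is.null(gy))
      vals[s] <- eval_scale(spec, gx, gy, scale = s, extra = extra)
  }
  new_ms_curve(seq_len(scales), vals, graining, spec, "XMSEn")
}

#' Composite and refined-composite multiscale cross-entropy (cXMSEn)
#'
#' Cross analogue of [cmsen()]: offset grains are applied to both series
#' in lockstep and averaged (composite) or pooled through the cross match
#' counts (refined-composite; XSampEn / XFuzzEn only).
#'
#' @inheritParams xmsen
#' @param refined pool cross match counts across offsets (default `FALSE`).
#' @return `ms_curve`.
#' @export
cxmsen <- function(x, y, spec, scales = 3L, refined = FALSE) {
  check_cross_spec(spec, "cxmsen")
  if (refined && !(spec$name %in% rc_supported))
    stop(sprintf(
      "refined-composite pooling needs per-level match counts; %s does not expose them (supported: %s)",
      spec$name, paste(intersect(rc_supported, cross_estimators()),
                       collapse = ", ")), call. = FALSE)
  scales <- check_positive_int(scales, "scales")
  p <- validate_pair(x, y)
  extra <- frozen_radius_extra(spec, p$x, p$y)
  vals <- rep(NA_real_, scales)
  for (s in seq_len(scales)) {
    gx <- lapply(0:(s - 1L), function(o) offset_grain(p$x, s, o))
    gy <- lapply(0:(s - 1L), function(o) offset_grain(p$y, s, o))
    if (any(vapply(c(gx, gy), length, integer(1)) < MIN_GRAINED_LENGTH)) {
      warning(sprintf("scale %d grains below %d samples; value missing", s,
                      MIN_GRAINED_LENGTH), call. = FALSE)
      next
    }
    vals[s] <- if (refined) rc_pool(spec, gx, gy, scale = s,
                                    extra = extra) else
      mean(vapply(seq_len(s), function(o)
        eval_scale(spec, gx[[o]], gy[[o]], scale = s, extra = extra),
        numeric(1)))
  }
  new_ms_curve(seq_len(scales), vals, "coarse", spec,
               if (refined) "rcXMSEn" else "cXMSEn")
}

#' Refined multiscale cross-entropy (rXMSEn)
#'
#' Cross analogue of [rmsen()]: the identical zero-phase Butterworth
#' low-pass (order 6, cutoff `0.5/s` of Nyquist) and decimation are
#' applied to both series; a free radius parameter is recomputed from the
#' pooled SD of the two filtered series at each scale.
#'
#' @inheritParams xmsen
#' @return `ms_curve`.
#' @export
rxmsen <- function(x, y, spec, scales = 3L) {
  check_cross_spec(spec, "rxmsen")
  scales <- check_positive_int(scales, "scales")
  p <- validate_pair(x, y)
  takes_r <- "r" %in% names(formals(cross_registry_map()[[spec$name]])) &&
    !("r" %in% names(spec$params))
  vals <- rep(NA_real_, scales)
  for (s in seq_len(scales)) {
    gx <- refined_rescale(p$x, s)
    gy <- refined_rescale(p$y, s)
    if (min(length(gx), length(gy)) < MIN_GRAINED_LENGTH) {
      warning(sprintf("scale %d leaves too few samples; value missing", s),
              call. = FALSE)
      next
    }
    extra <- if (takes_r) list(r = 0.2 * stats::sd(c(gx, gy))) else list()
    vals[s] <- eval_scale(make_spec(spec$name,
                                    utils::modifyList(spec$params, extra)),
                          gx, gy, scale = s)
  }
  new_ms_curve(seq_len(scales), vals, "butterworth", spec, "rXMSEn")
}

#' Hierarchical multiscale cross-entropy (hXMSEn)
#'
#' Cross analogue of [hmsen()]: the paired averaging/differencing tree is
#' built for each series and the cross estimator is evaluated on matched
#' node pairs.
#'
#' @inheritParams xmsen
#' @param depth tree depth (>= 0).
#' @return object of class `hms_tree`.
#' @export
hxmsen <- function(x, y, spec, depth = 2L) {
  check_cross_spec(spec, "hxmsen")
  depth <- check_positive_int(depth, "depth", min = 0L)
  p <- validate_pair(x, y)
  if (length(p$x) < 2^depth * MIN_GRAINED_LENGTH)
    stop(sprintf("series too short for depth %d: need n >= %d", depth,
                 2^depth * MIN_GRAINED_LENGTH), call. = FALSE)
  nx <- build_hier_tree(p$x, depth)
  ny <- build_hier_tree(p$y, depth)
  extra <- frozen_radius_extra(spec, p$x, p$y)
  layer <- floor(log2(seq_along(nx)))
  vals <- vapply(seq_along(nx), function(k)
    eval_scale(spec, nx[[k]], ny[[k]], scale = layer[k] + 1L,
               extra = extra), numeric(1))
  df <- data.frame(node = seq_along(nx), layer = layer,
                   type = ifelse(seq_along(nx) == 1L, "root",
                                 ifelse(seq_along(nx) %% 2L == 0L,
                                        "low", "high")),
                   n = vapply(nx, length, integer(1)), value = vals)
  structure(list(nodes = df, layer_means = tapply(vals, layer, mean),
                 series = nx, series_y = ny, spec = spec, depth = depth,
                 kind = "hXMSEn"),
            class = "hms_tree")
}
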