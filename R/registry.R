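# Estimator registries: the canonical name -> function maps for the 18
# base, 8 cross and 4 bidimensional estimators, plus validated dispatch.

base_registry_map <- function() {
  list(ApEn = apen, AttnEn = attnen, BubbEn = bubben, CondEn = conden,
       CoSiEn = cosien, DispEn = dispen, DistEn = disten, EnofEn = enofen,
       FuzzEn = fuzzen, GridEn = griden, IncrEn = incren, K2En = k2en,
       PermEn = permen, PhasEn = phasen, SampEn = sampen, SlopEn = slopen,
       SpecEn = specen, SyDyEn = sydyen)
}

cross_registry_map <- function() {
  list(XApEn = xapen, XCondEn = xconden, XDistEn = xdisten,
       XFuzzEn = xfuzzen, XK2En = xk2en, XPermEn = xpermen,
       XSampEn = xsampen, XSpecEn = xspecen)
}

bidim_registry_map <- function() {
  list(DispEn2D = dispen2d, DistEn2D = disten2d, FuzzEn2D = fuzzen2d,
       SampEn2D = sampen2d)
}

#' Registry of available estimators
#'
#' @param family `"base"`, `"cross"` or `"bidim"`.
#' @return character vector of estimator names in that family.
#' @examples
#' base_estimators()
#' @export
base_estimators <- function() names(base_registry_map())

#' @rdname base_estimators
#' @export
cross_estimators <- function() names(cross_registry_map())

#' @rdname base_estimators
#' @export
bidim_estimators <- function() names(bidim_registry_map())

dispatch_registry <- function(map, family, name, args) {
  fn <- map[[name]]
  known <- names(formals(fn))
  bad <- setdiff(names(args), known)
  if (length(bad))
    stop(sprintf("invalid parameter(s) for %s: %s (accepted: %s)", name,
                 paste(bad, collapse = ", "),
                 paste(setdiff(known, c("x", "y", "img")), collapse = ", ")),
         call. = FALSE)
  fn
}

#' Run a base estimator by name
#'
#' Validated dispatch into the 18-estimator base registry; unknown names
#' raise an error listing the valid names, and unknown parameters are
#' rejected by name before any computation.
#'
#' @param name estimator id, one of [base_estimators()].
#' @param x numeric time series.
#' @param ... estimator parameters passed through.
#' @return [entropy_result].
#' @examples
#' set.seed(1)
#' base_entropy("SampEn", rnorm(100))
#' @export
base_entropy <- function(name, x, ...) {
  map <- base_registry_map()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(map)))
    stop(sprintf("unknown base estimator '%s'; valid names: %s",
                 as.character(name)[1],
                 paste(names(map), collapse = ", ")), call. = FALSE)
  args <- list(...)
  fn <- dispatch_registry(map, "base", name, args)
  do.call(fn, c(list(x), args))
}

#' Run a cross estimator by name
#'
#' @param name estimator id, one of [cross_estimators()].
#' @param x,y the paired numeric series.
#' @param ... estimator parameters passed through.
#' @return [entropy_result].
#' @export
cross_entropy_fn <- function(name, x, y, ...) {
  map <- cross_registry_map()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(map)))
    stop(sprintf("unknown cross estimator '%s'; valid names: %s",
                 as.character(name)[1],
                 paste(names(map), collapse = ", ")), call. = FALSE)
  args <- list(...)
  fn <- dispatch_registry(map, "cross", name, args)
  do.call(fn, c(list(x, y), args))
}

#' Run a bidimensional estimator by name
#'
#' @param name estimator id, one of [bidim_estimators()].
#' @param img numeric matrix.
#' @param ... estimator parameters passed through.
#' @return [entropy_result].
#' @export
bidim_entropy <- function(name, img, ...) {
  map <- bidim_registry_map()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(map)))
    stop(sprintf("unknown bidimensional estimator '%s'; valid names: %s",
                 as.character(name)[1],
                 paste(names(map), collapse = ", ")), call. = FALSE)
  args <- list(...)
  fn <- dispatch_registry(map, "bidimensional", name, args)
  do.call(fn, c(list(img), args))
}
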