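# Shared primitives: validation, delay embedding, symbolisation,
# histogramming, and the Shannon/conditional entropy kernels that every
# estimator ultimately reduces to.

MIN_SERIES_LENGTH <- 10L

#' Validate a univariate time series
#'
#' Checks that `x` is a finite numeric vector of at least `min_length`
#' samples, in time order. Used by every estimator entry point.
#'
#' @param x numeric vector.
#' @param min_length minimum admissible length (default 10).
#' @param arg name used in error messages.
#' @return the validated numeric vector, invisibly unchanged.
#' @export
validate_series <- function(x, min_length = MIN_SERIES_LENGTH, arg = "x") {
  if (!is.numeric(x) || is.matrix(x))
    stop(sprintf("`%s` must be a numeric vector", arg), call. = FALSE)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` contains missing or non-finite values", arg),
         call. = FALSE)
  if (length(x) < min_length)
    stop(sprintf("`%s` has %d samples; at least %d are required", arg,
                 length(x), min_length), call. = FALSE)
  invisible(x)
}

validate_matrix <- function(x, m = 2L, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` contains missing or non-finite values", arg),
         call. = FALSE)
  if (nrow(x) < m || ncol(x) < m)
    stop(sprintf("`%s` is %dx%d; both dimensions must be >= template size %d",
                 arg, nrow(x), ncol(x), m), call. = FALSE)
  invisible(x)
}

check_positive_int <- function(v, arg, min = 1L) {
  if (length(v) != 1L || !is.numeric(v) || !is.finite(v) ||
      v != round(v) || v < min)
    stop(sprintf("`%s` must be a single integer >= %d", arg, min),
         call. = FALSE)
  as.integer(v)
}

#' Construct an entropy result
#'
#' Container returned by every estimator: the primary estimate (scalar or
#' level vector), named secondary outputs, and the complete resolved
#' parameter set (defaults included) used for the computation.
#'
#' @param estimator estimator name (registry id).
#' @param primary numeric scalar or vector of estimates.
#' @param secondary named list of auxiliary outputs.
#' @param params named list recording every parameter that was applied.
#' @return an object of class `entropy_result`.
#' @export
entropy_result <- function(estimator, primary, secondary = list(),
                           params = list()) {
  structure(list(estimator = estimator, primary = primary,
                 secondary = secondary, params = params),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result: %s>\n", x$estimator))
  cat("  primary:  ", paste(signif(x$primary, 6), collapse = " "), "\n")
  if (length(x$secondary))
    cat("  secondary:", paste(names(x$secondary), collapse = ", "), "\n")
  pp <- x$params[!vapply(x$params, is.null, logical(1))]
  kv <- vapply(seq_along(pp), function(i) {
    v <- pp[[i]]
    paste0(names(pp)[i], "=", paste(format(unlist(v), digits = 4),
                                    collapse = ","))
  }, character(1))
  if (length(kv)) cat("  params:   ", paste(kv, collapse = " "), "\n")
  invisible(x)
}

#' Shannon entropy of a discrete distribution
#'
#' Computes `-sum(p * log(p, base))` with the convention `0 * log(0) = 0`.
#'
#' @param p vector of probability masses (non-negative, summing to 1 within
#'   1e-12).
#' @param log_base logarithm base (default natural log).
#' @return non-negative entropy in units of `log_base`.
#' @examples
#' shannon_entropy(rep(0.25, 4), log_base = 2) # 2 bits
#' @export
shannon_entropy <- function(p, log_base = exp(1)) {
  if (any(p < 0)) stop("probability masses must be non-negative",
                       call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12)
    stop("probability masses must sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log(p)) / log(log_base)
}

#' Conditional entropy H(X | Y) from a joint table
#'
#' @param joint matrix of joint probabilities `p(x, y)` with X on rows and Y
#'   on columns; must be normalised.
#' @param log_base logarithm base.
#' @return `H(X, Y) - H(Y)`, which is >= 0 and <= H(X).
#' @export
conditional_entropy <- function(joint, log_base = exp(1)) {
  if (!is.matrix(joint)) stop("`joint` must be a matrix", call. = FALSE)
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-12)
    stop("`joint` must be a normalised probability table", call. = FALSE)
  hxy <- shannon_entropy(as.vector(joint), log_base)
  hy <- shannon_entropy(colSums(joint), log_base)
  hxy - hy
}

#' Time-delay embedding
#'
#' Builds the matrix of delay vectors `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`
#' used by template-matching estimators. Row `i` starts at sample `i`; the
#' matrix has `n - (m - 1) * tau` rows.
#'
#' @param x numeric vector.
#' @param m embedding dimension (columns).
#' @param tau time delay in samples.
#' @return numeric matrix with `m` columns.
#' @examples
#' delay_embed(1:5, m = 2, tau = 1)
#' @export
delay_embed <- function(x, m, tau = 1L) {
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  n <- length(x)
  k <- n - (m - 1L) * tau
  if (k < 1L)
    stop(sprintf(
      "series too short for embedding: need n > (m-1)*tau = %d, have n = %d",
      (m - 1L) * tau, n), call. = FALSE)
  idx <- outer(seq_len(k), (seq_len(m) - 1L) * tau, `+`)
  matrix(x[idx], nrow = k, ncol = m)
}

metric_code <- function(metric = c("chebyshev", "euclidean")) {
  match(match.arg(metric), c("chebyshev", "euclidean")) - 1L
}

#' Count template pairs within a radius
#'
#' Symmetric count of unordered row pairs of an embedding matrix whose
#' distance does not exceed `r`; the kernel behind the sample/approximate
#' entropy family. Also returns per-row neighbour counts.
#'
#' @param emb embedding matrix (rows = templates).
#' @param r radius, >= 0.
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @param exclude_self if `TRUE` (default) self-pairs are not counted in the
#'   per-row counts.
#' @return list with `pairs` (total count of unordered within-r pairs) and
#'   `per_row` (neighbour count per template).
#' @export
match_counts <- function(emb, r, metric = c("chebyshev", "euclidean"),
                         exclude_self = TRUE) {
  if (!is.matrix(emb)) emb <- matrix(emb, ncol = 1L)
  if (!is.numeric(r) || length(r) != 1L || r < 0)
    stop("`r` must be a single non-negative number", call. = FALSE)
  mc <- metric_code(metric)
  per_row <- row_neighbour_counts(emb, r, mc, !exclude_self)
  pairs <- pair_count_within(emb, r, mc, nrow(emb))
  list(pairs = pairs, per_row = per_row)
}

#' Symbolise a series with the normal cumulative distribution function
#'
#' Maps samples to integer classes `1..c` by standardising the series,
#' applying the standard normal CDF, and slicing `(0, 1)` into `c` equal
#' intervals: `class = min(c, floor(c * z) + 1)`. A constant series (zero
#' standard deviation) maps every sample to the middle class
#' `ceiling(c / 2)`.
#'
#' @param x numeric vector (or matrix, flattened column-wise with statistics
#'   taken over all entries).
#' @param c number of symbol classes, >= 2.
#' @return integer vector (or matrix matching `x`) of classes in `1..c`.
#' @export
ncdf_symbolise <- function(x, c = 3L) {
  c <- check_positive_int(c, "c", min = 2L)
  v <- as.numeric(x)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    cls <- rep(as.integer(ceiling(c / 2)), length(v))
  } else {
    z <- stats::pnorm((v - mean(v)) / s)
    cls <- pmin(c, pmax(1L, floor(c * z) + 1L))
  }
  if (is.matrix(x)) matrix(as.integer(cls), nrow(x), ncol(x))
  else as.integer(cls)
}

#' Histogram probability masses
#'
#' Equal-width histogram over `[min, max]` with Sturges' rule
#' (`ceiling(log2(n)) + 1` bins) or a fixed bin count; returns the
#' occupancy probabilities. All-identical input collapses to a single bin
#' with mass 1.
#'
#' @param values numeric vector, length >= 2.
#' @param binning `"sturges"` or a positive integer bin count.
#' @return list with `p` (masses summing to 1), `breaks`, and `n_bins`.
#' @export
histogram_probs <- function(values, binning = "sturges") {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2])
    return(list(p = 1, breaks = c(rng[1], rng[2]), n_bins = 1L))
  if (identical(binning, "sturges")) {
    k <- as.integer(ceiling(log2(length(values))) + 1)
  } else {
    k <- check_positive_int(binning, "binning")
  }
  breaks <- seq(rng[1], rng[2], length.out = k + 1L)
  cnt <- tabulate(pmin(k, findInterval(values, breaks, left.open = FALSE)),
                  nbins = k)
  list(p = cnt / sum(cnt), breaks = breaks, n_bins = k)
}

# Entropy of an observed symbol census (counts), natural log by default.
census_entropy <- function(counts, log_base = exp(1)) {
  if (!length(counts) || sum(counts) == 0) return(0)
  shannon_entropy(counts / sum(counts), log_base)
}

# Radius default 0.2 * SD (n-1 denominator), shared across estimators.
default_radius <- function(x, scale = 0.2) {
  s <- stats::sd(x)
  if (!is.finite(s)) s <- 0
  if (s == 0)
    warning("series has zero standard deviation; radius default is 0",
            call. = FALSE)
  scale * s
}
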