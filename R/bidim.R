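# Bidimensional (image) estimators over sliding square submatrix
# templates. Only fully in-bounds templates are used (no padding). The
# pair-matching estimators are quadratic in the template count, so
# matrices larger than 128 x 128 require an explicit override.

COST_GUARD_EDGE <- 128L

check_cost_guard <- function(img, override) {
  if (!override && (nrow(img) > COST_GUARD_EDGE || ncol(img) > COST_GUARD_EDGE))
    stop(sprintf(
      "matrix is %dx%d; pair matching is quadratic in template count, pass override = TRUE to run matrices larger than %dx%d",
      nrow(img), ncol(img), COST_GUARD_EDGE, COST_GUARD_EDGE), call. = FALSE)
  invisible(TRUE)
}

# rows = flattened m x m templates at lattice delay tau; positions are
# row-major over the (H - (m-1)tau) x (W - (m-1)tau) valid grid.
bidim_templates <- function(img, m, tau, nh = NULL, nw = NULL) {
  if (is.null(nh)) nh <- nrow(img) - (m - 1L) * tau
  if (is.null(nw)) nw <- ncol(img) - (m - 1L) * tau
  if (nh < 1L || nw < 1L)
    stop(sprintf("template size %d at delay %d exceeds the %dx%d matrix",
                 m, tau, nrow(img), ncol(img)), call. = FALSE)
  out <- matrix(0, nh * nw, m * m)
  k <- 1L
  ri <- seq(0L, by = tau, length.out = m)
  for (i in seq_len(nh)) {
    for (j in seq_len(nw)) {
      out[k, ] <- as.vector(img[i + ri, j + ri])
      k <- k + 1L
    }
  }
  out
}

#' Bidimensional dispersion entropy (DispEn2D)
#'
#' Dispersion entropy of an image: the whole matrix is symbolised with the
#' normal-CDF transform into `c` classes (statistics taken over all
#' entries), every fully in-bounds `m x m` dispersion pattern at lattice
#' delay `tau` is collected, and the Shannon entropy of the pattern census
#' is returned in nats (unnormalised by default, as in the source
#' literature; `normalise = TRUE` divides by `log(c^(m^2))`).
#'
#' @param img numeric matrix.
#' @param m template edge length, >= 2 (default 2).
#' @param tau lattice delay (default 1).
#' @param c number of symbol classes (default 3).
#' @param normalise divide by `log(c^(m^2))` (default `FALSE`).
#' @param log_base logarithm base (default natural log).
#' @return [entropy_result]; secondary `n_patterns` (distinct patterns) and
#'   `n_templates`.
#' @examples
#' set.seed(1)
#' dispen2d(matrix(rnorm(300), 15, 20), m = 2)
#' @export
dispen2d <- function(img, m = 2L, tau = 1L, c = 3L, normalise = FALSE,
                     log_base = exp(1)) {
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  c <- check_positive_int(c, "c", min = 2L)
  validate_matrix(img, m)
  sym <- ncdf_symbolise(img, c)
  nh <- nrow(img) - (m - 1L) * tau
  nw <- ncol(img) - (m - 1L) * tau
  tmpl <- bidim_templates(sym, m, tau, nh, nw)
  pats <- apply(tmpl, 1L, paste, collapse = ".")
  counts <- table(pats)
  H <- census_entropy(counts, log_base)
  if (normalise) H <- H / (m^2 * log(c) / log(log_base))
  entropy_result("DispEn2D", H,
                 list(n_patterns = length(counts), n_templates = nh * nw),
                 list(m = m, tau = tau, c = c, normalise = normalise,
                      log_base = log_base))
}

#' Bidimensional sample entropy (SampEn2D)
#'
#' Sample entropy of an image: `B` counts unordered pairs of `m x m`
#' templates within Chebyshev distance `r` of each other (self-pairs
#' excluded), `A` the `(m+1) x (m+1)` analogue; both counts are taken over
#' the positions at which the larger template fits, and the estimate is
#' `-log(A / B)`.
#'
#' @inheritParams dispen2d
#' @param r radius; default `0.2 * sd(img)` over all entries.
#' @param override run matrices larger than 128 x 128 despite the
#'   quadratic cost (default `FALSE`).
#' @return [entropy_result]; secondary `A`, `B`.
#' @export
sampen2d <- function(img, m = 2L, tau = 1L, r = NULL, override = FALSE,
                     log_base = exp(1)) {
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  validate_matrix(img, m + 1L)
  check_cost_guard(img, override)
  if (is.null(r)) r <- default_radius(as.numeric(img))
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  nh <- nrow(img) - m * tau
  nw <- ncol(img) - m * tau
  tm <- bidim_templates(img, m, tau, nh, nw)
  tm1 <- bidim_templates(img, m + 1L, tau, nh, nw)
  B <- pair_count_within(tm, r, 0L, nrow(tm))
  A <- pair_count_within(tm1, r, 0L, nrow(tm1))
  est <- if (A == 0 || B == 0) {
    warning("no template matches; returning Inf", call. = FALSE)
    Inf
  } else -log(A / B) / log(log_base)
  entropy_result("SampEn2D", est, list(A = A, B = B),
                 list(m = m, tau = tau, r = r, log_base = log_base))
}

#' Bidimensional fuzzy entropy (FuzzEn2D)
#'
#' [sampen2d()] with the hard threshold replaced by a fuzzy membership of
#' the inter-template distance (default `exp(-d^p / r)`), templates
#' centred before comparison.
#'
#' @inheritParams sampen2d
#' @inheritParams fuzzen
#' @return [entropy_result]; secondary `phi`.
#' @export
fuzzen2d <- function(img, m = 2L, tau = 1L, r = NULL, p = 2,
                     membership = fuzzy_memberships, override = FALSE,
                     log_base = exp(1)) {
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  membership <- match.arg(membership)
  type <- match(membership, fuzzy_memberships) - 1L
  validate_matrix(img, m + 1L)
  check_cost_guard(img, override)
  if (is.null(r)) r <- default_radius(as.numeric(img))
  if (r <= 0) stop("`r` must be > 0 for fuzzy memberships", call. = FALSE)
  nh <- nrow(img) - m * tau
  nw <- ncol(img) - m * tau
  tm <- bidim_templates(img, m, tau, nh, nw)
  tm1 <- bidim_templates(img, m + 1L, tau, nh, nw)
  tm <- tm - rowMeans(tm)
  tm1 <- tm1 - rowMeans(tm1)
  phi_m <- fuzzy_pair_sum(tm, r, p, type, 0L, nrow(tm)) /
    (nrow(tm) * (nrow(tm) - 1) / 2)
  phi_m1 <- fuzzy_pair_sum(tm1, r, p, type, 0L, nrow(tm1)) /
    (nrow(tm1) * (nrow(tm1) - 1) / 2)
  est <- (log(phi_m) - log(phi_m1)) / log(log_base)
  entropy_result("FuzzEn2D", est, list(phi = c(phi_m, phi_m1)),
                 list(m = m, tau = tau, r = r, p = p,
                      membership = membership, log_base = log_base))
}

#' Bidimensional distribution entropy (DistEn2D)
#'
#' Distribution entropy of an image: the histogram of all inter-template
#' Chebyshev distances between `m x m` templates, scored by normalised
#' Shannon entropy in \[0, 1\].
#'
#' @inheritParams sampen2d
#' @param binning `"sturges"` (default) or a fixed positive bin count.
#' @param normalise divide by `log(n_bins)` (default `TRUE`).
#' @return [entropy_result]; secondary `n_bins`.
#' @export
disten2d <- function(img, m = 2L, tau = 1L, binning = "sturges",
                     normalise = TRUE, override = FALSE,
                     log_base = exp(1)) {
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  validate_matrix(img, m)
  check_cost_guard(img, override)
  tm <- bidim_templates(img, m, tau)
  d <- pairwise_dists(tm, 0L, nrow(tm))
  h <- histogram_probs(d, binning)
  H <- shannon_entropy(h$p, log_base)
  if (normalise && h$n_bins > 1L) H <- H / (log(h$n_bins) / log(log_base))
  entropy_result("DistEn2D", H, list(n_bins = h$n_bins),
                 list(m = m, tau = tau, binning = binning,
                      normalise = normalise, log_base = log_base))
}
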