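# Template-matching regularity estimators: approximate, sample, fuzzy and
# Kolmogorov (K2) entropy. All share the delay-embedding + neighbour-count
# kernel; distances are Chebyshev except K2 (Euclidean, as in the
# correlation-integral literature).

#' Approximate entropy (ApEn)
#'
#' Pincus' approximate entropy. For each level `k`, `Phi(k)` is the mean
#' log of the self-inclusive frequency with which `k`-dimensional delay
#' vectors lie within `r` of each other (Chebyshev distance); the level-`k`
#' estimate is `Phi(k) - Phi(k + 1)` with the convention `Phi(0) = 0`.
#' The returned vector holds levels `0..m`; the final element is the usual
#' ApEn(m) estimate. High values indicate irregular, unpredictable series;
#' Gaussian white noise with default parameters scores above 2 nats.
#'
#' @param x numeric time series (length >= 10).
#' @param m embedding dimension (default 2).
#' @param tau time delay in samples (default 1).
#' @param r tolerance radius; default `0.2 * sd(x)`.
#' @param log_base logarithm base (default natural log).
#' @return [entropy_result] with `primary` = vector of `m + 1` estimates for
#'   levels `0..m` and secondary `phi` = the `Phi(1..m+1)` values.
#' @examples
#' set.seed(1)
#' apen(rnorm(300))
#' @export
apen <- function(x, m = 2L, tau = 1L, r = NULL, log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  if (is.null(r)) r <- default_radius(x)
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  n <- length(x)
  if (n <= m * tau)
    stop(sprintf("series too short: need n > m*tau = %d", m * tau),
         call. = FALSE)
  phi <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    emb <- delay_embed(x, k, tau)
    cnt <- row_neighbour_counts(emb, r, 0L, TRUE)
    phi[k] <- mean(log(cnt / nrow(emb)))
  }
  ap <- (c(0, phi[seq_len(m)]) - phi) / log(log_base)
  entropy_result("ApEn", ap, list(phi = phi / log(log_base)),
                 list(m = m, tau = tau, r = r, log_base = log_base))
}

#' Sample entropy (SampEn)
#'
#' Richman and Moorman's sample entropy: `-log(A / B)` where `B` counts
#' unordered pairs of `m`-dimensional templates within `r` (Chebyshev,
#' self-matches excluded) and `A` the `(m + 1)`-dimensional analogue. Both
#' counts at level `k` are taken over the `n - k * tau` templates whose
#' `(k + 1)`-point extension exists. Levels `0..m` are returned; level 0
#' compares all sample pairs against `B = n(n-1)/2`.
#'
#' If `A` or `B` is zero the level estimate is `Inf` with a warning (short
#' series), never an error, so batch runs are not aborted.
#'
#' @inheritParams apen
#' @return [entropy_result]; `primary` = estimates for levels `0..m`,
#'   secondary `A`, `B` = the per-level match counts.
#' @examples
#' set.seed(1)
#' sampen(rnorm(300))
#' @export
sampen <- function(x, m = 2L, tau = 1L, r = NULL, log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  if (is.null(r)) r <- default_radius(x)
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  n <- length(x)
  if (n <= m * tau)
    stop(sprintf("series too short: need n > m*tau = %d", m * tau),
         call. = FALSE)
  A <- B <- numeric(m + 1L)
  for (k in 0:m) {
    n_use <- n - k * tau
    B[k + 1L] <- if (k == 0) n * (n - 1) / 2 else
      pair_count_within(delay_embed(x, k, tau), r, 0L, n_use)
    A[k + 1L] <- pair_count_within(delay_embed(x, k + 1L, tau), r, 0L, n_use)
  }
  est <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    if (B[k] == 0 || A[k] == 0) {
      warning(sprintf(
        "no template matches at level %d (A=%g, B=%g); returning Inf",
        k - 1L, A[k], B[k]), call. = FALSE)
      est[k] <- Inf
    } else est[k] <- -log(A[k] / B[k]) / log(log_base)
  }
  entropy_result("SampEn", est, list(A = A, B = B),
                 list(m = m, tau = tau, r = r, log_base = log_base))
}

fuzzy_memberships <- c("default-exponential", "gaussian", "triangular",
                       "sigmoid")

#' Fuzzy entropy (FuzzEn)
#'
#' Sample-entropy variant in which the hard radius threshold is replaced by
#' a fuzzy membership of the inter-template distance, and templates are
#' centred (mean-subtracted) before comparison. The default membership is
#' the exponential family `mu(d) = exp(-d^p / r)` with exponent `p = 2`.
#' Levels `1..m` are returned; level `k` is
#' `log(phi_k) - log(phi_{k+1})` where `phi_k` is the mean membership over
#' template pairs.
#'
#' @inheritParams apen
#' @param membership one of `"default-exponential"`, `"gaussian"`,
#'   `"triangular"`, `"sigmoid"`.
#' @param p membership exponent/shape parameter (default 2).
#' @return [entropy_result]; `primary` = levels `1..m`, secondary `phi` =
#'   mean membership per level `1..m+1`.
#' @examples
#' set.seed(1)
#' fuzzen(rnorm(200))
#' @export
fuzzen <- function(x, m = 2L, tau = 1L, r = NULL, p = 2,
                   membership = fuzzy_memberships, log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  membership <- match.arg(membership)
  type <- match(membership, fuzzy_memberships) - 1L
  if (is.null(r)) r <- default_radius(x)
  if (r <= 0) stop("`r` must be > 0 for fuzzy memberships", call. = FALSE)
  n <- length(x)
  if (n <= m * tau)
    stop(sprintf("series too short: need n > m*tau = %d", m * tau),
         call. = FALSE)
  phi <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    emb <- delay_embed(x, k, tau)
    emb <- emb - rowMeans(emb)
    n_use <- if (k <= m) n - k * tau else nrow(emb)
    npairs <- n_use * (n_use - 1) / 2
    phi[k] <- fuzzy_pair_sum(emb, r, p, type, 0L, n_use) / npairs
  }
  est <- (log(phi[seq_len(m)]) - log(phi[-1L])) / log(log_base)
  entropy_result("FuzzEn", est, list(phi = phi),
                 list(m = m, tau = tau, r = r, p = p,
                      membership = membership, log_base = log_base))
}

#' Kolmogorov (K2) entropy
#'
#' Grassberger-Procaccia correlation-sum estimate of the K2 entropy:
#' `K2(k) = log(C_k(r) / C_{k+1}(r))` where `C_k(r)` is the fraction of
#' template pairs within Euclidean distance `r` at embedding dimension
#' `k`. Levels `1..m` are returned; a vanishing correlation sum yields
#' `Inf` with a warning.
#'
#' @inheritParams apen
#' @return [entropy_result]; `primary` = levels `1..m`, secondary
#'   `correlation_sums` = `C_1..C_{m+1}`.
#' @examples
#' set.seed(1)
#' k2en(rnorm(200))
#' @export
k2en <- function(x, m = 2L, tau = 1L, r = NULL, log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  if (is.null(r)) r <- default_radius(x)
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  n <- length(x)
  if (n <= m * tau)
    stop(sprintf("series too short: need n > m*tau = %d", m * tau),
         call. = FALSE)
  cs <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    emb <- delay_embed(x, k, tau)
    nk <- nrow(emb)
    cs[k] <- pair_count_within(emb, r, 1L, nk) / (nk * (nk - 1) / 2)
  }
  est <- numeric(m)
  for (k in seq_len(m)) {
    if (cs[k] == 0 || cs[k + 1L] == 0) {
      warning(sprintf("zero correlation sum at level %d; returning Inf", k),
              call. = FALSE)
      est[k] <- Inf
    } else est[k] <- log(cs[k] / cs[k + 1L]) / log(log_base)
  }
  entropy_result("K2En", est, list(correlation_sums = cs),
                 list(m = m, tau = tau, r = r, log_base = log_base))
}
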