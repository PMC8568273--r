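# Cross-entropy estimators: shared-regularity statistics between two
# series. Templates are drawn from one series and matched in the other;
# there is no self-match concept. The default radius for radius-based
# methods is 0.2 x the pooled SD of both series.

validate_pair <- function(x, y, allow_unequal = FALSE) {
  x <- validate_series(x, arg = "x")
  y <- validate_series(y, arg = "y")
  if (!allow_unequal && length(x) != length(y))
    stop(sprintf(
      "series lengths differ (%d vs %d); set allow_unequal = TRUE where the method permits",
      length(x), length(y)), call. = FALSE)
  list(x = x, y = y)
}

pooled_radius <- function(x, y, scale = 0.2) {
  s <- stats::sd(c(x, y))
  if (!is.finite(s) || s == 0) {
    warning("pooled standard deviation is zero; radius default is 0",
            call. = FALSE)
    s <- 0
  }
  scale * s
}

#' Cross-sample entropy (XSampEn)
#'
#' Sample entropy over cross-matches only: `B` counts pairs of an
#' `m`-dimensional template from `x` and one from `y` within `r`
#' (Chebyshev), `A` the `(m+1)`-dimensional analogue, and the level
#' estimate is `-log(A / B)`. Symmetric in `(x, y)`. Levels `0..m` are
#' returned (level 0 compares raw samples). `XSampEn(x, x)` equals sample
#' entropy computed with self-matches retained.
#'
#' @param x,y paired numeric series (equal length unless
#'   `allow_unequal = TRUE`).
#' @inheritParams apen
#' @param r radius; default `0.2 * sd(c(x, y))` (pooled).
#' @param allow_unequal accept series of different lengths.
#' @return [entropy_result] with secondary match counts `A`, `B`.
#' @examples
#' set.seed(1)
#' xsampen(rnorm(100), rnorm(100))
#' @export
xsampen <- function(x, y, m = 2L, tau = 1L, r = NULL,
                    allow_unequal = FALSE, log_base = exp(1)) {
  p <- validate_pair(x, y, allow_unequal)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  if (is.null(r)) r <- pooled_radius(p$x, p$y)
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  nx <- length(p$x); ny <- length(p$y)
  if (min(nx, ny) <= m * tau)
    stop(sprintf("series too short: need n > m*tau = %d", m * tau),
         call. = FALSE)
  A <- B <- numeric(m + 1L)
  for (k in 0:m) {
    nux <- nx - k * tau; nuy <- ny - k * tau
    B[k + 1L] <- if (k == 0) as.numeric(nx) * ny else
      cross_count_within(delay_embed(p$x, k, tau)[seq_len(nux), , drop = FALSE],
                         delay_embed(p$y, k, tau)[seq_len(nuy), , drop = FALSE],
                         r, 0L)
    A[k + 1L] <- cross_count_within(delay_embed(p$x, k + 1L, tau),
                                    delay_embed(p$y, k + 1L, tau), r, 0L)
  }
  est <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    if (B[k] == 0 || A[k] == 0) {
      warning(sprintf("no cross-matches at level %d; returning Inf", k - 1L),
              call. = FALSE)
      est[k] <- Inf
    } else est[k] <- -log(A[k] / B[k]) / log(log_base)
  }
  entropy_result("XSampEn", est, list(A = A, B = B),
                 list(m = m, tau = tau, r = r, log_base = log_base))
}

#' Cross-approximate entropy (XApEn)
#'
#' Approximate entropy over cross-match frequencies. Directional by
#' construction: templates are taken from the first series and matched
#' against the pool of templates from the second (the convention is
#' recorded in `params$direction`); swap the arguments for the reverse
#' direction. Levels `0..m` with `Phi(0) = 0` as in [apen()].
#'
#' @inheritParams xsampen
#' @return [entropy_result] with secondary `phi`.
#' @export
xapen <- function(x, y, m = 2L, tau = 1L, r = NULL,
                  allow_unequal = FALSE, log_base = exp(1)) {
  p <- validate_pair(x, y, allow_unequal)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  if (is.null(r)) r <- pooled_radius(p$x, p$y)
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  if (min(length(p$x), length(p$y)) <= m * tau)
    stop(sprintf("series too short: need n > m*tau = %d", m * tau),
         call. = FALSE)
  phi <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    ex <- delay_embed(p$x, k, tau)
    ey <- delay_embed(p$y, k, tau)
    cnt <- cross_neighbour_counts(ex, ey, r, 0L)
    if (any(cnt == 0))
      warning(sprintf(
        "template(s) from `x` with no match in `y` at level %d", k),
        call. = FALSE)
    phi[k] <- mean(log(cnt / nrow(ey)))
  }
  est <- (c(0, phi[seq_len(m)]) - phi) / log(log_base)
  entropy_result("XApEn", est, list(phi = phi / log(log_base)),
                 list(m = m, tau = tau, r = r, log_base = log_base,
                      direction = "templates from x matched in y"))
}

#' Cross-permutation entropy (XPermEn)
#'
#' Ordinal-pattern coupling between aligned windows: each length-`m`
#' window of `x` and the simultaneous window of `y` are reduced to their
#' rank patterns, and the statistic is the conditional Shannon entropy
#' `H(pattern_y | pattern_x)` of the joint census. Bounded by
#' `[0, log(m!)]`; 0 when `y`'s ordinal structure is determined by `x`'s
#' (e.g. identical series), and near `log(m!)` for independent series.
#'
#' @inheritParams xsampen
#' @param m window length, >= 2 (default 3).
#' @return [entropy_result] with secondary `H_joint` and `H_x`.
#' @export
xpermen <- function(x, y, m = 3L, tau = 1L, log_base = exp(1)) {
  p <- validate_pair(x, y, allow_unequal = FALSE)
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  ex <- delay_embed(p$x, m, tau)
  ey <- delay_embed(p$y, m, tau)
  px <- ordinal_patterns(ex)
  py <- ordinal_patterns(ey)
  joint <- table(px, py)
  h_joint <- census_entropy(joint, log_base)
  h_x <- census_entropy(table(px), log_base)
  entropy_result("XPermEn", h_joint - h_x,
                 list(H_joint = h_joint, H_x = h_x),
                 list(m = m, tau = tau, log_base = log_base))
}

#' Cross-distribution entropy (XDistEn)
#'
#' Distribution entropy of the cross-distance set: Chebyshev distances
#' between every `m`-dimensional template of `x` and every template of
#' `y`, histogrammed (Sturges' rule by default) and scored by normalised
#' Shannon entropy in \[0, 1\]. Symmetric in `(x, y)`.
#'
#' @inheritParams xsampen
#' @param binning `"sturges"` (default) or a fixed positive bin count.
#' @param normalise divide by `log(n_bins)` (default `TRUE`).
#' @return [entropy_result]; secondary `n_bins`.
#' @export
xdisten <- function(x, y, m = 2L, tau = 1L, binning = "sturges",
                    normalise = TRUE, allow_unequal = FALSE,
                    log_base = exp(1)) {
  p <- validate_pair(x, y, allow_unequal)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  d <- cross_dists(delay_embed(p$x, m, tau), delay_embed(p$y, m, tau), 0L)
  h <- histogram_probs(d, binning)
  H <- shannon_entropy(h$p, log_base)
  if (normalise && h$n_bins > 1L) H <- H / (log(h$n_bins) / log(log_base))
  entropy_result("XDistEn", H, list(n_bins = h$n_bins),
                 list(m = m, tau = tau, binning = binning,
                      normalise = normalise, log_base = log_base))
}

#' Cross-fuzzy entropy (XFuzzEn)
#'
#' Fuzzy entropy over cross pairs: templates of both series are centred,
#' compared by Chebyshev distance through a fuzzy membership (default
#' `exp(-d^p / r)`), and the level-`k` estimate is
#' `log(phi_k) - log(phi_{k+1})` with `phi_k` the mean cross membership.
#' Levels `1..m`.
#'
#' @inheritParams xsampen
#' @inheritParams fuzzen
#' @return [entropy_result]; secondary `phi`.
#' @export
xfuzzen <- function(x, y, m = 2L, tau = 1L, r = NULL, p = 2,
                    membership = fuzzy_memberships, allow_unequal = FALSE,
                    log_base = exp(1)) {
  pr <- validate_pair(x, y, allow_unequal)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  membership <- match.arg(membership)
  type <- match(membership, fuzzy_memberships) - 1L
  if (is.null(r)) r <- pooled_radius(pr$x, pr$y)
  if (r <= 0) stop("`r` must be > 0 for fuzzy memberships", call. = FALSE)
  nx <- length(pr$x); ny <- length(pr$y)
  if (min(nx, ny) <= m * tau)
    stop(sprintf("series too short: need n > m*tau = %d", m * tau),
         call. = FALSE)
  phi <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    ex <- delay_embed(pr$x, k, tau); ex <- ex - rowMeans(ex)
    ey <- delay_embed(pr$y, k, tau); ey <- ey - rowMeans(ey)
    if (k <= m) {
      ex <- ex[seq_len(nx - k * tau), , drop = FALSE]
      ey <- ey[seq_len(ny - k * tau), , drop = FALSE]
    }
    phi[k] <- fuzzy_cross_sum(ex, ey, r, p, type, 0L) /
      (nrow(ex) * nrow(ey))
  }
  est <- (log(phi[seq_len(m)]) - log(phi[-1L])) / log(log_base)
  entropy_result("XFuzzEn", est, list(phi = phi),
                 list(m = m, tau = tau, r = r, p = p,
                      membership = membership, log_base = log_base))
}

#' Cross-conditional entropy (XCondEn)
#'
#' Corrected conditional entropy of one series' next symbol given the
#' other's recent symbolic past. Both series are quantised into `c`
#' equal-width bins over their own ranges; words pair a length-`(k-1)`
#' symbol pattern from `x` with the next symbol of `y`. The corrected
#' conditional entropy adds `perc(k) * H_1(y)` (singleton-word fraction)
#' as in [conden()]. Returned vector: `(H_1(y), CCE(2), ..., CCE(m))`.
#'
#' @inheritParams xsampen
#' @param c number of amplitude bins (default 6).
#' @param normalise divide by `H_1(y)` (default `FALSE`).
#' @export
xconden <- function(x, y, m = 2L, tau = 1L, c = 6L, normalise = FALSE,
                    log_base = exp(1)) {
  p <- validate_pair(x, y, allow_unequal = FALSE)
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  c <- check_positive_int(c, "c", min = 2L)
  quantise <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(1L, length(v)))
    pmin(c, floor((v - rng[1]) / ((rng[2] - rng[1]) / c)) + 1L)
  }
  sx <- quantise(p$x); sy <- quantise(p$y)
  n <- length(sx)
  H <- perc <- numeric(m)
  tab1 <- table(sy)
  H[1L] <- census_entropy(tab1, log_base)
  perc[1L] <- sum(tab1 == 1L) / sum(tab1)
  for (k in 2:m) {
    ex <- delay_embed(sx, k - 1L, tau)
    last <- n - (k - 1L) * tau
    ex <- ex[seq_len(last), , drop = FALSE]
    ynext <- sy[seq_len(last) + (k - 1L) * tau]
    words <- paste(apply(ex, 1L, paste, collapse = "."), ynext, sep = "|")
    tab <- table(words)
    H[k] <- census_entropy(tab, log_base)
    perc[k] <- sum(tab == 1L) / sum(tab)
  }
  out <- numeric(m)
  out[1L] <- H[1L]
  for (k in 2:m) out[k] <- (H[k] - H[k - 1L]) + perc[k] * H[1L]
  if (normalise && H[1L] > 0) out <- out / H[1L]
  entropy_result("XCondEn", out, list(H = H, singleton_fraction = perc),
                 list(m = m, tau = tau, c = c, normalise = normalise,
                      log_base = log_base))
}

#' Cross-Kolmogorov entropy (XK2En)
#'
#' Correlation-sum K2 estimate built from cross pairs only: `C_k(r)` is
#' the fraction of (x-template, y-template) pairs within Euclidean
#' distance `r`, and the level estimate is `log(C_k / C_{k+1})`. This
#' cross analogue has no published validation in the source literature;
#' results are flagged `unverified` in `params`.
#'
#' @inheritParams xsampen
#' @return [entropy_result]; secondary `correlation_sums`.
#' @export
xk2en <- function(x, y, m = 2L, tau = 1L, r = NULL,
                  allow_unequal = FALSE, log_base = exp(1)) {
  p <- validate_pair(x, y, allow_unequal)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  if (is.null(r)) r <- pooled_radius(p$x, p$y)
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  if (min(length(p$x), length(p$y)) <= m * tau)
    stop(sprintf("series too short: need n > m*tau = %d", m * tau),
         call. = FALSE)
  cs <- numeric(m + 1L)
  for (k in seq_len(m + 1L)) {
    ex <- delay_embed(p$x, k, tau)
    ey <- delay_embed(p$y, k, tau)
    cs[k] <- cross_count_within(ex, ey, r, 1L) / (nrow(ex) * nrow(ey))
  }
  est <- numeric(m)
  for (k in seq_len(m)) {
    if (cs[k] == 0 || cs[k + 1L] == 0) {
      warning(sprintf("zero cross correlation sum at level %d; returning Inf",
                      k), call. = FALSE)
      est[k] <- Inf
    } else est[k] <- log(cs[k] / cs[k + 1L]) / log(log_base)
  }
  entropy_result("XK2En", est, list(correlation_sums = cs),
                 list(m = m, tau = tau, r = r, log_base = log_base,
                      unverified = TRUE))
}

#' Cross-spectral entropy (XSpecEn)
#'
#' Shannon entropy of the normalised magnitude of the one-sided cross
#' spectrum `fft(x) * Conj(fft(y))`, divided by the log bin count.
#' Symmetric in `(x, y)`. Like [xk2en()], this analogue of the univariate
#' spectral entropy is flagged `unverified` in `params` as it has no
#' published validation.
#'
#' @inheritParams xsampen
#' @return [entropy_result].
#' @export
xspecen <- function(x, y, log_base = exp(1)) {
  p <- validate_pair(x, y, allow_unequal = FALSE)
  n <- length(p$x)
  pxy <- Mod(stats::fft(p$x) * Conj(stats::fft(p$y)))[seq_len(floor(n / 2) + 1L)]
  if (sum(pxy) == 0)
    stop("cross spectrum is identically zero", call. = FALSE)
  pr <- pxy / sum(pxy)
  H <- shannon_entropy(pr, log_base) / (log(length(pr)) / log(log_base))
  entropy_result("XSpecEn", H, list(),
                 list(log_base = log_base, unverified = TRUE))
}
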