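# Distribution-shaped estimators: distribution entropy, entropy of entropy,
# attention entropy, cosine similarity entropy and bubble entropy.

#' Distribution entropy (DistEn)
#'
#' Li's distribution entropy: the Shannon entropy of the histogram of all
#' inter-template Chebyshev distances, normalised by the log bin count so
#' the value lies in \[0, 1\]. Unlike sample entropy it has no radius
#' parameter; the shape of the whole distance distribution is scored.
#'
#' @inheritParams apen
#' @param binning `"sturges"` (default) or a fixed positive bin count.
#' @param normalise divide by `log(n_bins)` (default `TRUE`).
#' @return [entropy_result]; secondary `n_bins`.
#' @examples
#' set.seed(1)
#' disten(rnorm(100))
#' @export
disten <- function(x, m = 2L, tau = 1L, binning = "sturges",
                   normalise = TRUE, log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  emb <- delay_embed(x, m, tau)
  d <- pairwise_dists(emb, 0L, nrow(emb))
  h <- histogram_probs(d, binning)
  H <- shannon_entropy(h$p, log_base)
  if (normalise && h$n_bins > 1L)
    H <- H / (log(h$n_bins) / log(log_base))
  entropy_result("DistEn", H, list(n_bins = h$n_bins),
                 list(m = m, tau = tau, binning = binning,
                      normalise = normalise, log_base = log_base))
}

#' Entropy of entropy (EnofEn)
#'
#' Hsu's two-level entropy: the series is cut into consecutive windows of
#' `win` samples; within each window the Shannon entropy of the sample
#' occupancy over `slices` amplitude bins (spanning the global range) is
#' computed; the entropy of the distribution of those window entropies is
#' returned. Captures variability of local state occupancy over time.
#'
#' @inheritParams apen
#' @param win window length in samples (default 10).
#' @param slices number of amplitude slices over the global range
#'   (default 10).
#' @return [entropy_result]; secondary `mean_window_entropy` and
#'   `window_entropies`.
#' @export
enofen <- function(x, win = 10L, slices = 10L, log_base = exp(1)) {
  x <- validate_series(x)
  win <- check_positive_int(win, "win", min = 2L)
  slices <- check_positive_int(slices, "slices", min = 2L)
  nw <- floor(length(x) / win)
  if (nw < 2L)
    stop("series too short: need at least 2 full windows", call. = FALSE)
  rng <- range(x)
  wins <- matrix(x[seq_len(nw * win)], nrow = win)
  went <- apply(wins, 2L, function(w) {
    if (rng[1] == rng[2]) return(0)
    cls <- pmin(slices, floor((w - rng[1]) / ((rng[2] - rng[1]) / slices)) + 1L)
    census_entropy(tabulate(cls, nbins = slices), log_base)
  })
  eoe <- census_entropy(table(signif(went, 12)), log_base)
  entropy_result("EnofEn", eoe,
                 list(mean_window_entropy = mean(went),
                      window_entropies = went),
                 list(win = win, slices = slices, log_base = log_base))
}

#' Attention entropy (AttnEn)
#'
#' Yang's attention entropy scores only the key patterns of a series - its
#' strict local maxima and minima. Four interval sequences are formed
#' (max-max, min-min, max-min, min-max event gaps) and the Shannon entropy
#' of each interval census is computed; the primary output is their mean.
#' A series with no peaks (e.g. constant or monotone) scores 0.
#'
#' @inheritParams apen
#' @return [entropy_result]; secondary the four interval entropies.
#' @export
attnen <- function(x, log_base = exp(1)) {
  x <- validate_series(x)
  n <- length(x)
  core <- 2:(n - 1L)
  is_max <- c(FALSE, x[core] > x[core - 1L] & x[core] > x[core + 1L], FALSE)
  is_min <- c(FALSE, x[core] < x[core - 1L] & x[core] < x[core + 1L], FALSE)
  imax <- which(is_max); imin <- which(is_min)
  gap_entropy <- function(v) {
    if (length(v) < 2L) return(0)
    census_entropy(table(diff(v)), log_base)
  }
  cross_gaps <- function(from, to) {
    # gap from each `from` event to the next `to` event
    if (!length(from) || !length(to)) return(numeric(0))
    nxt <- findInterval(from, to) + 1L
    ok <- nxt <= length(to)
    to[nxt[ok]] - from[ok]
  }
  cross_entropy_of <- function(g) {
    if (length(g) < 1L) return(0)
    census_entropy(table(g), log_base)
  }
  h <- c(max_max = gap_entropy(imax),
         min_min = gap_entropy(imin),
         max_min = cross_entropy_of(cross_gaps(imax, imin)),
         min_max = cross_entropy_of(cross_gaps(imin, imax)))
  entropy_result("AttnEn", mean(h), as.list(h), list(log_base = log_base))
}

#' Cosine similarity entropy (CoSiEn)
#'
#' Chanwimalueang-Mandic estimator: delay vectors are compared by angular
#' distance `acos(cos_sim) / pi`; `B` is the fraction of template pairs
#' with angular distance below `r`, and the estimate is the binary Shannon
#' entropy `-B log B - (1 - B) log(1 - B)`. Insensitive to amplitude, it
#' targets self-correlation structure.
#'
#' @inheritParams apen
#' @param r angular-distance threshold in \[0, 1\] (default 0.1).
#' @return [entropy_result]; secondary `B` = matched-pair fraction.
#' @export
cosien <- function(x, m = 2L, tau = 1L, r = 0.1, log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  if (r <= 0 || r >= 1) stop("`r` must lie in (0, 1)", call. = FALSE)
  emb <- delay_embed(x, m, tau)
  nr <- sqrt(rowSums(emb^2))
  k <- nrow(emb)
  dots <- tcrossprod(emb)
  denom <- outer(nr, nr)
  cosm <- ifelse(denom == 0, 1, pmin(1, pmax(-1, dots / denom)))
  ang <- acos(cosm) / pi
  B <- sum(ang[upper.tri(ang)] <= r) / (k * (k - 1) / 2)
  H <- 0
  for (pr in c(B, 1 - B)) if (pr > 0) H <- H - pr * log(pr)
  entropy_result("CoSiEn", H / log(log_base), list(B = B),
                 list(m = m, tau = tau, r = r, log_base = log_base))
}

#' Bubble entropy (BubbEn)
#'
#' Manis' bubble entropy ranks windows by how far they are from sorted
#' order: the number of inversions (bubble-sort swaps) in each window of
#' length `k`. `H2(k)` is the Renyi order-2 entropy of the swap-count
#' distribution, and the level-`k` estimate is
#' `(H2(k+1) - H2(k)) / log((k+1)/(k-1))`, returned for `k = 2..m`.
#' Almost parameter-free (no radius), robust to the choice of `m`.
#'
#' @inheritParams apen
#' @param m maximum embedding dimension, >= 2 (default 2).
#' @return [entropy_result]; secondary `H2` = Renyi-2 entropies for
#'   dimensions `2..m+1`.
#' @export
bubben <- function(x, m = 2L, tau = 1L, log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  n_inversions <- function(w) {
    s <- 0L
    for (i in seq_len(length(w) - 1L))
      s <- s + sum(w[i] > w[(i + 1L):length(w)])
    s
  }
  dims <- 2:(m + 1L)
  H2 <- numeric(length(dims))
  for (di in seq_along(dims)) {
    emb <- delay_embed(x, dims[di], tau)
    sw <- apply(emb, 1L, n_inversions)
    p <- as.numeric(table(sw)) / length(sw)
    H2[di] <- -log(sum(p^2)) / log(log_base)
  }
  est <- (H2[-1L] - H2[-length(H2)]) /
    (log((dims[-1L] - 1L + 1L) / (dims[-1L] - 1L - 1L)) / log(log_base))
  entropy_result("BubbEn", est, list(H2 = H2),
                 list(m = m, tau = tau, log_base = log_base))
}
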