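# Symbol-sequence estimators: permutation entropy and its variants,
# dispersion, slope, increment, symbolic-dynamic and corrected conditional
# entropy. Each maps the series to a discrete symbol stream and scores the
# Shannon entropy of an m-symbol word census.

permen_variants <- c("classic", "edge", "weighted", "amplitude-aware",
                     "modified", "fine-grained", "uniform-quantization")

# ordinal pattern ids for the rows of an embedding matrix; ties broken by
# earlier index ranking lower (stable order()).
ordinal_patterns <- function(emb) {
  apply(emb, 1L, function(w) paste(order(w), collapse = "."))
}

# number of weak orderings (rankings with ties) of k items; alphabet size of
# the modified (tie-aware) permutation variant.
ordered_bell <- function(k) {
  a <- numeric(k + 1L); a[1L] <- 1
  for (n in seq_len(k))
    a[n + 1L] <- sum(vapply(seq_len(n), function(i)
      choose(n, i) * a[n - i + 1L], numeric(1)))
  a[k + 1L]
}

#' Permutation entropy (PermEn) and variants
#'
#' Bandt-Pompe ordinal-pattern entropy. Each window of `k` samples
#' (`k = 2..m`) is reduced to its rank permutation (ties broken by the
#' earlier index ranking lower) and the Shannon entropy of the pattern
#' census is returned per embedding order. The normalised form divides by
#' `log(k!)` (or by the log alphabet size of the variant).
#'
#' Variants reweight or requantise the census:
#' * `weighted` — windows weighted by their (population) variance.
#' * `amplitude-aware` — weight `(A/k) sum|x| + ((1-A)/(k-1)) sum|dx|`,
#'   `A = 0.5`.
#' * `edge` — weight `(mean |dx|)^r_exp`, emphasising steep windows.
#' * `modified` — tied samples share a rank, enlarging the alphabet to the
#'   weak orderings of `k` items.
#' * `fine-grained` — pattern extended by the quantised window amplitude
#'   `floor(max|dx| / (alpha * sd(x)))`.
#' * `uniform-quantization` — windows of symbols from a uniform `L`-level
#'   amplitude quantiser replace the rank patterns.
#'
#' @inheritParams apen
#' @param m maximum embedding order, >= 2 (default 2).
#' @param variant one of `r paste(permen_variants, collapse=", ")`.
#' @param A amplitude-aware mixing weight in \[0, 1\] (default 0.5).
#' @param r_exp edge-variant weight exponent (default 1).
#' @param alpha fine-grained quantisation factor (default 1).
#' @param L uniform-quantization level count (default 4).
#' @return [entropy_result]; `primary` = entropy per order `2..m`,
#'   secondary `normalised` (per order) and `census` (order `m`).
#' @examples
#' set.seed(1)
#' permen(rnorm(200), m = 3)
#' @export
permen <- function(x, m = 2L, tau = 1L, variant = permen_variants,
                   log_base = exp(1), A = 0.5, r_exp = 1, alpha = 1, L = 4L) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  variant <- match.arg(variant)
  n <- length(x)
  if (n <= (m - 1L) * tau)
    stop(sprintf("series too short: need n > (m-1)*tau = %d", (m - 1L) * tau),
         call. = FALSE)
  orders <- 2:m
  H <- Hn <- numeric(length(orders))
  census <- NULL
  for (oi in seq_along(orders)) {
    k <- orders[oi]
    emb <- delay_embed(x, k, tau)
    w <- rep(1, nrow(emb))
    if (variant == "modified") {
      pat <- apply(emb, 1L, function(v)
        paste(rank(v, ties.method = "min"), collapse = "."))
      alph <- ordered_bell(k)
    } else if (variant == "uniform-quantization") {
      rng <- range(x)
      q <- if (rng[1] == rng[2]) matrix(1L, nrow(emb), k) else {
        qq <- floor((emb - rng[1]) / ((rng[2] - rng[1]) / L)) + 1L
        qq[qq > L] <- L
        qq
      }
      pat <- apply(q, 1L, paste, collapse = ".")
      alph <- L^k
    } else if (variant == "fine-grained") {
      base_pat <- ordinal_patterns(emb)
      s <- stats::sd(x)
      amp <- if (s == 0) rep(0, nrow(emb)) else
        floor(apply(abs(emb[, -1L, drop = FALSE] -
                          emb[, -k, drop = FALSE]), 1L, max) / (alpha * s))
      pat <- paste(base_pat, amp, sep = "|")
      alph <- NA_real_  # unbounded alphabet; normalise by observed size
    } else {
      pat <- ordinal_patterns(emb)
      alph <- factorial(k)
      if (variant == "weighted") {
        w <- apply(emb, 1L, function(v) mean((v - mean(v))^2))
      } else if (variant == "amplitude-aware") {
        dsum <- rowSums(abs(emb[, -1L, drop = FALSE] -
                              emb[, -k, drop = FALSE]))
        w <- (A / k) * rowSums(abs(emb)) + ((1 - A) / (k - 1)) * dsum
      } else if (variant == "edge") {
        w <- (rowSums(abs(emb[, -1L, drop = FALSE] -
                            emb[, -k, drop = FALSE])) / (k - 1))^r_exp
      }
    }
    if (all(w == 0)) w <- rep(1, length(w))  # degenerate weights
    mass <- tapply(w, pat, sum)
    H[oi] <- census_entropy(mass, log_base)
    denom <- if (is.na(alph)) max(1, length(mass)) else alph
    Hn[oi] <- if (denom <= 1) 0 else H[oi] / (log(denom) / log(log_base))
    if (k == m) census <- sort(mass, decreasing = TRUE)
  }
  entropy_result("PermEn", H,
                 list(normalised = Hn, census = census),
                 list(m = m, tau = tau, variant = variant,
                      log_base = log_base, A = A, r_exp = r_exp,
                      alpha = alpha, L = L))
}

#' Dispersion entropy (DispEn)
#'
#' Rostaghi-Azami dispersion entropy: the series is mapped to `c` classes
#' with the normal-CDF transform ([ncdf_symbolise]), the class series is
#' delay-embedded, and the Shannon entropy of the dispersion-pattern census
#' is returned (natural log, unnormalised by default). The secondary output
#' is the reverse dispersion entropy
#' `RDE = sum((p_i - c^-m)^2)` over all `c^m` possible patterns, a
#' distance-from-white-noise measure that is 0 for a uniform pattern
#' distribution.
#'
#' @inheritParams apen
#' @param c number of symbol classes (default 3).
#' @param normalise divide by `log(c^m)` (default `FALSE`).
#' @return [entropy_result]; secondary `rde` and `n_patterns`.
#' @examples
#' set.seed(1)
#' dispen(rnorm(200))
#' @export
dispen <- function(x, m = 2L, tau = 1L, c = 3L, normalise = FALSE,
                   log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  c <- check_positive_int(c, "c", min = 2L)
  sym <- ncdf_symbolise(x, c)
  emb <- delay_embed(sym, m, tau)
  pat <- apply(emb, 1L, paste, collapse = ".")
  counts <- table(pat)
  p <- as.numeric(counts) / sum(counts)
  H <- census_entropy(counts, log_base)
  if (normalise) H <- H / (log(c^m) / log(log_base))
  rde <- sum(p^2) - 1 / c^m
  entropy_result("DispEn", H,
                 list(rde = rde, n_patterns = length(counts)),
                 list(m = m, tau = tau, c = c, normalise = normalise,
                      log_base = log_base))
}

#' Slope entropy (SlopEn)
#'
#' Cuesta-Frau's slope entropy. Consecutive increments are mapped to five
#' symbols using two slope thresholds given in degrees (default 5 and 45):
#' `0` for |slope| <= tan(lvls[1]), `+/-1` for intermediate, `+/-2` for
#' |slope| > tan(lvls[2]). Words of `m - 1` symbols are censused and their
#' Shannon entropy returned; the normalised form divides by the log of the
#' `5^(m-1)`-word alphabet.
#'
#' @inheritParams apen
#' @param lvls two increasing slope thresholds in degrees (default `c(5, 45)`).
#' @param normalise divide by `log(5^(m-1))` (default `TRUE`).
#' @export
slopen <- function(x, m = 2L, tau = 1L, lvls = c(5, 45), normalise = TRUE,
                   log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  if (length(lvls) != 2L || lvls[1] <= 0 || lvls[2] <= lvls[1])
    stop("`lvls` must be two increasing positive angles in degrees",
         call. = FALSE)
  t1 <- tan(lvls[1] * pi / 180); t2 <- tan(lvls[2] * pi / 180)
  d <- x[-seq_len(tau)] - x[seq_len(length(x) - tau)]
  sym <- integer(length(d))
  sym[abs(d) > t1 & abs(d) <= t2] <- 1L
  sym[abs(d) > t2] <- 2L
  sym <- sym * sign(d)
  words <- apply(delay_embed(sym, m - 1L, tau), 1L, paste, collapse = ".")
  H <- census_entropy(table(words), log_base)
  if (normalise) H <- H / (log(5^(m - 1L)) / log(log_base))
  entropy_result("SlopEn", H, list(n_words = length(unique(words))),
                 list(m = m, tau = tau, lvls = lvls, normalise = normalise,
                      log_base = log_base))
}

#' Increment entropy (IncrEn)
#'
#' Liu's increment entropy. Each first difference is coded by its sign and
#' a quantised magnitude `q = min(R, floor(|dx| * R / sd(dx)))`; words of
#' `m` consecutive sign*magnitude codes are censused and their Shannon
#' entropy returned. The normalised form divides by `(m) * log(2R + 1)`.
#'
#' @inheritParams apen
#' @param R quantifying resolution (default 4).
#' @param normalise divide by `m * log(2R + 1)` (default `FALSE`).
#' @export
incren <- function(x, m = 2L, tau = 1L, R = 4L, normalise = FALSE,
                   log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  R <- check_positive_int(R, "R")
  d <- x[-seq_len(tau)] - x[seq_len(length(x) - tau)]
  s <- stats::sd(d)
  q <- if (!is.finite(s) || s == 0) rep(0L, length(d)) else
    pmin(R, floor(abs(d) * R / s))
  code <- sign(d) * q
  words <- apply(delay_embed(code, m, tau), 1L, paste, collapse = ".")
  H <- census_entropy(table(words), log_base)
  if (normalise) H <- H / (m * log(2 * R + 1) / log(log_base))
  entropy_result("IncrEn", H, list(n_words = length(unique(words))),
                 list(m = m, tau = tau, R = R, normalise = normalise,
                      log_base = log_base))
}

#' Symbolic dynamic entropy (SyDyEn)
#'
#' The series is partitioned into `c` symbols by maximum-entropy
#' partitioning (equal-occupancy quantile bins), and the entropy of the
#' joint census of (length-`m` state word, next symbol) is returned - the
#' sum of the state-pattern entropy and the conditional state-transition
#' entropy. Normalised by `log(c^(m+1))` by default.
#'
#' @inheritParams apen
#' @param c number of symbols (default 3).
#' @param normalise divide by `log(c^(m+1))` (default `TRUE`).
#' @export
sydyen <- function(x, m = 2L, tau = 1L, c = 3L, normalise = TRUE,
                   log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m")
  tau <- check_positive_int(tau, "tau")
  c <- check_positive_int(c, "c", min = 2L)
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = c + 1L),
                        names = FALSE)
  if (qs[1] == qs[c + 1L]) {
    sym <- rep(1L, length(x))
  } else {
    sym <- pmin(c, pmax(1L, findInterval(x, qs, rightmost.closed = TRUE)))
  }
  words <- apply(delay_embed(sym, m + 1L, tau), 1L, paste, collapse = ".")
  H <- census_entropy(table(words), log_base)
  if (normalise) H <- H / (log(c^(m + 1L)) / log(log_base))
  entropy_result("SyDyEn", H, list(n_words = length(unique(words))),
                 list(m = m, tau = tau, c = c, normalise = normalise,
                      log_base = log_base))
}

#' Corrected conditional entropy (CondEn)
#'
#' Porta's corrected conditional entropy. The series is quantised into `c`
#' equal-width amplitude bins; `H_k` is the Shannon entropy of length-`k`
#' words. The conditional entropy `CE(k) = H_k - H_{k-1}` is corrected by
#' adding `perc(k) * H_1`, where `perc(k)` is the fraction of length-`k`
#' words observed exactly once (the correction counteracts the spurious
#' decrease of CE with word length in short series). The returned vector is
#' `(H_1, CCE(2), ..., CCE(m))`.
#'
#' @inheritParams apen
#' @param c number of amplitude bins (default 6).
#' @param normalise divide by `H_1` (default `FALSE`).
#' @export
conden <- function(x, m = 2L, tau = 1L, c = 6L, normalise = FALSE,
                   log_base = exp(1)) {
  x <- validate_series(x)
  m <- check_positive_int(m, "m", min = 2L)
  tau <- check_positive_int(tau, "tau")
  c <- check_positive_int(c, "c", min = 2L)
  rng <- range(x)
  sym <- if (rng[1] == rng[2]) rep(1L, length(x)) else
    pmin(c, floor((x - rng[1]) / ((rng[2] - rng[1]) / c)) + 1L)
  H <- perc <- numeric(m)
  for (k in seq_len(m)) {
    words <- apply(delay_embed(sym, k, tau), 1L, paste, collapse = ".")
    tab <- table(words)
    H[k] <- census_entropy(tab, log_base)
    perc[k] <- sum(tab == 1L) / sum(tab)
  }
  out <- numeric(m)
  out[1L] <- H[1L]
  for (k in 2:m) out[k] <- (H[k] - H[k - 1L]) + perc[k] * H[1L]
  if (normalise && H[1L] > 0) out <- out / H[1L]
  entropy_result("CondEn", out, list(H = H, singleton_fraction = perc),
                 list(m = m, tau = tau, c = c, normalise = normalise,
                      log_base = log_base))
}
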