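# Brute-force oracles, written as plain double loops independent of the
# package kernels. Each mirrors the published definition directly.

cheb <- function(a, b) max(abs(a - b))
eucl <- function(a, b) sqrt(sum((a - b)^2))

embed_rows <- function(x, m, tau) {
  k <- length(x) - (m - 1) * tau
  out <- matrix(0, k, m)
  for (i in seq_len(k)) out[i, ] <- x[i + (seq_len(m) - 1) * tau]
  out
}

oracle_pair_count <- function(emb, r, dist = cheb) {
  n <- nrow(emb); cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (dist(emb[i, ], emb[j, ]) <= r) cnt <- cnt + 1
  cnt
}

oracle_apen <- function(x, m, tau, r) {
  n <- length(x)
  phi <- numeric(m + 1)
  for (k in seq_len(m + 1)) {
    emb <- embed_rows(x, k, tau)
    nk <- nrow(emb)
    ci <- vapply(seq_len(nk), function(i)
      sum(vapply(seq_len(nk), function(j)
        cheb(emb[i, ], emb[j, ]) <= r, logical(1))) / nk, numeric(1))
    phi[k] <- mean(log(ci))
  }
  c(0, phi[seq_len(m)]) - phi
}

oracle_sampen <- function(x, m, tau, r) {
  n <- length(x)
  est <- numeric(m + 1)
  for (k in 0:m) {
    nu <- n - k * tau
    B <- if (k == 0) n * (n - 1) / 2 else
      oracle_pair_count(embed_rows(x, k, tau)[seq_len(nu), , drop = FALSE], r)
    A <- oracle_pair_count(embed_rows(x, k + 1, tau), r)
    est[k + 1] <- if (A == 0 || B == 0) Inf else -log(A / B)
  }
  est
}

oracle_fuzzen <- function(x, m, tau, r, p = 2) {
  n <- length(x)
  phi <- numeric(m + 1)
  for (k in seq_len(m + 1)) {
    emb <- embed_rows(x, k, tau)
    emb <- emb - rowMeans(emb)
    nu <- if (k <= m) n - k * tau else nrow(emb)
    s <- 0
    for (i in seq_len(nu - 1)) for (j in (i + 1):nu)
      s <- s + exp(-cheb(emb[i, ], emb[j, ])^p / r)
    phi[k] <- s / (nu * (nu - 1) / 2)
  }
  log(phi[seq_len(m)]) - log(phi[-1])
}

oracle_k2en <- function(x, m, tau, r) {
  cs <- vapply(seq_len(m + 1), function(k) {
    emb <- embed_rows(x, k, tau)
    oracle_pair_count(emb, r, eucl) / (nrow(emb) * (nrow(emb) - 1) / 2)
  }, numeric(1))
  ifelse(cs[seq_len(m)] == 0 | cs[-1] == 0, Inf,
         log(cs[seq_len(m)] / cs[-1]))
}

oracle_xsampen <- function(x, y, m, tau, r) {
  n <- length(x)
  est <- numeric(m + 1)
  cross_count <- function(ex, ey) {
    cnt <- 0
    for (i in seq_len(nrow(ex))) for (j in seq_len(nrow(ey)))
      if (cheb(ex[i, ], ey[j, ]) <= r) cnt <- cnt + 1
    cnt
  }
  for (k in 0:m) {
    nu <- n - k * tau
    B <- if (k == 0) n * n else
      cross_count(embed_rows(x, k, tau)[seq_len(nu), , drop = FALSE],
                  embed_rows(y, k, tau)[seq_len(nu), , drop = FALSE])
    A <- cross_count(embed_rows(x, k + 1, tau), embed_rows(y, k + 1, tau))
    est[k + 1] <- if (A == 0 || B == 0) Inf else -log(A / B)
  }
  est
}

oracle_sampen2d_counts <- function(img, m, tau, r) {
  templ <- function(mm) {
    nh <- nrow(img) - (mm - 1) * tau
    nw <- ncol(img) - (mm - 1) * tau
    out <- list(); k <- 1
    for (i in seq_len(nh)) for (j in seq_len(nw)) {
      out[[k]] <- img[i + (seq_len(mm) - 1) * tau,
                      j + (seq_len(mm) - 1) * tau]
      k <- k + 1
    }
    out
  }
  count_pairs <- function(tl) {
    cnt <- 0
    for (i in seq_len(length(tl) - 1)) for (j in (i + 1):length(tl))
      if (max(abs(tl[[i]] - tl[[j]])) <= r) cnt <- cnt + 1
    cnt
  }
  # both levels restricted to positions where the (m+1) template fits
  nh <- nrow(img) - m * tau; nw <- ncol(img) - m * tau
  tm <- list(); k <- 1
  for (i in seq_len(nh)) for (j in seq_len(nw)) {
    tm[[k]] <- img[i + (seq_len(m) - 1) * tau, j + (seq_len(m) - 1) * tau]
    k <- k + 1
  }
  list(B = count_pairs(tm), A = count_pairs(templ(m + 1)))
}

# exhaustive ordinal-pattern census (ties: earlier index ranks lower)
oracle_perm_census <- function(x, m, tau) {
  emb <- embed_rows(x, m, tau)
  table(apply(emb, 1, function(w) paste(order(w), collapse = ".")))
}

shannon_nats <- function(counts) {
  p <- counts / sum(counts); p <- p[p > 0]
  -sum(p * log(p))
}
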