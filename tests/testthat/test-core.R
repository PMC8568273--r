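# Shared primitives: entropy kernels, embedding, matching, symbolisation,
# histogramming.

test_that("shannon_entropy matches closed forms and rejects bad masses", {
  expect_equal(shannon_entropy(rep(0.25, 4), log_base = 2), 2)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25), log_base = 2), 1.5)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), log(2))  # 0 log 0 = 0
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("uniform distribution maximises shannon_entropy", {
  set.seed(11)
  for (k in c(3, 5, 8)) {
    hmax <- shannon_entropy(rep(1 / k, k))
    expect_equal(hmax, log(k))
    for (rep_i in 1:10) {
      p <- runif(k); p <- p / sum(p)
      expect_lte(shannon_entropy(p), hmax + 1e-12)
    }
  }
})

test_that("conditional_entropy agrees with direct sums and its bounds", {
  # independence: H(X|Y) = H(X)
  joint <- outer(c(0.5, 0.5), c(0.3, 0.7))
  expect_equal(conditional_entropy(joint, log_base = 2), 1)
  # deterministic copy: H(X|Y) = 0
  expect_equal(conditional_entropy(diag(2) / 2), 0)
  set.seed(21)
  for (i in 1:25) {
    j <- matrix(runif(9), 3); j <- j / sum(j)
    # brute force over all cells
    hxy <- -sum(j * log(j))
    hy <- {p <- colSums(j); -sum(p * log(p))}
    hx <- {p <- rowSums(j); -sum(p * log(p))}
    expect_equal(conditional_entropy(j), hxy - hy, tolerance = 1e-12)
    expect_gte(conditional_entropy(j), -1e-12)
    expect_lte(conditional_entropy(j), hx + 1e-12)
  }
})

test_that("delay_embed lays out rows correctly and enforces length", {
  expect_equal(delay_embed(1:5, 2, 1),
               matrix(c(1, 2, 3, 4, 2, 3, 4, 5), ncol = 2))
  expect_equal(delay_embed(1:5, 1, 1), matrix(1:5, ncol = 1))
  expect_equal(delay_embed(1:6, 2, 2),
               matrix(c(1, 2, 3, 4, 3, 4, 5, 6), ncol = 2))
  expect_error(delay_embed(1:5, 6, 1), "too short")
  # row-count formula across a parameter sweep
  set.seed(5)
  x <- rnorm(60)
  for (m in 1:4) for (tau in 1:3) {
    if (length(x) - (m - 1) * tau < 1) next
    expect_identical(nrow(delay_embed(x, m, tau)),
                     as.integer(length(x) - (m - 1) * tau))
  }
})

test_that("match_counts equals the exhaustive pair oracle", {
  expect_equal(match_counts(matrix(1, 7, 3), r = 0)$pairs, 7 * 6 / 2)
  expect_equal(match_counts(matrix(1:10, 5, 2), r = 0)$pairs, 0)
  set.seed(31)
  for (i in 1:200) {
    k <- sample(5:50, 1)
    d <- sample(1:4, 1)
    emb <- matrix(rnorm(k * d), k, d)
    r <- runif(1, 0.1, 2)
    expect_identical(match_counts(emb, r)$pairs, oracle_pair_count(emb, r))
  }
})

test_that("ncdf_symbolise follows the NCDF slicing and degenerate rules", {
  expect_true(all(ncdf_symbolise(rep(3.2, 50), c = 3) == 2L))
  x <- c(rnorm(99), 1e6)
  expect_identical(ncdf_symbolise(x, 3)[100], 3L)
  # class proportions approach the NCDF tertiles for standard-normal input
  set.seed(41)
  props <- rowMeans(vapply(1:25, function(i) {
    cls <- ncdf_symbolise(rnorm(3000), 3)
    tabulate(cls, 3) / 3000
  }, numeric(3)))
  expect_equal(props, rep(1 / 3, 3), tolerance = 0.02)
})

test_that("histogram_probs implements Sturges and sums to one", {
  h <- histogram_probs(runif(4096))
  expect_identical(h$n_bins, 13L)
  expect_equal(sum(h$p), 1)
  expect_equal(histogram_probs(rep(2, 5))$p, 1)
  set.seed(51)
  h2 <- histogram_probs(runif(1000), binning = 10L)
  expect_lt(max(abs(h2$p - 0.1)), 0.03)
})
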