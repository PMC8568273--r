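# Distribution-shaped and geometric estimators, plus registry dispatch.

test_that("DistEn matches a direct distance-histogram oracle", {
  set.seed(301)
  for (i in 1:10) {
    x <- rnorm(30)
    emb <- embed_rows(x, 2, 1)
    d <- c()
    for (a in seq_len(nrow(emb) - 1)) for (b in (a + 1):nrow(emb))
      d <- c(d, cheb(emb[a, ], emb[b, ]))
    brk <- seq(min(d), max(d), length.out = 11)
    cnt <- tabulate(pmin(10, findInterval(d, brk)), 10)
    expect_equal(disten(x, binning = 10L)$primary,
                 shannon_nats(cnt) / log(10), tolerance = 1e-12)
  }
  expect_equal(disten(rep(3, 30))$primary, 0)
  set.seed(302)
  for (i in 1:100) {
    v <- disten(rnorm(sample(30:80, 1)))$primary
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("SpecEn separates tones from noise and matches a direct DFT", {
  tone <- sin(2 * pi * 8 * (0:255) / 256)
  expect_lt(specen(tone)$primary, 1e-10)
  # white noise approaches the flat-spectrum limit; the exponential
  # periodogram distribution leaves a deficit of (1 - gamma)/log(n_bins)
  set.seed(303)
  vals <- vapply(1:25, function(i) specen(rnorm(4096))$primary, numeric(1))
  expect_gt(mean(vals), 0.9)
  expect_lt(mean(vals), 1)
  # 16-sample direct transform oracle
  x <- rnorm(16)
  pw <- abs(fft(x))^2
  p <- pw[1:9] / sum(pw[1:9])
  expect_equal(specen(x)$primary, shannon_nats(p * 1e6) / log(9),
               tolerance = 1e-9)
  # band restriction
  res <- specen(tone, band = c(0.01, 0.1))
  expect_true(res$secondary$band_specen >= 0)
  expect_error(specen(tone, band = c(0.4, 0.2)), "increasing")
})

test_that("EnofEn scores flat windows as zero and records window entropies", {
  expect_equal(enofen(rep(1, 50))$primary, 0)
  set.seed(304)
  x <- rnorm(500)
  res <- enofen(x)
  expect_length(res$secondary$window_entropies, 50)
  expect_gte(res$primary, 0)
  expect_equal(res$secondary$mean_window_entropy,
               mean(res$secondary$window_entropies))
})

test_that("AttnEn measures peak-interval diversity", {
  # strict alternation: every interior point is a peak or trough,
  # all intervals identical -> zero entropy
  alt <- rep(c(0, 1), 25)
  expect_equal(attnen(alt)$primary, 0)
  set.seed(305)
  expect_gt(attnen(rnorm(500))$primary, 0.5)
})

test_that("CoSiEn is amplitude-insensitive and zero for aligned templates", {
  expect_equal(cosien(rep(2, 40))$primary, 0)
  set.seed(306)
  x <- abs(rnorm(200)) + 1
  expect_equal(cosien(x)$primary, cosien(3 * x)$primary, tolerance = 1e-12)
  expect_gte(cosien(rnorm(200))$primary, 0)
})

test_that("BubbEn follows the inversion-count Renyi construction", {
  expect_equal(bubben(rep(1, 40))$primary, 0)
  set.seed(307)
  x <- rnorm(60)
  res <- bubben(x, m = 3)
  expect_length(res$primary, 2)
  expect_length(res$secondary$H2, 3)
  # H2 recomputed from an exhaustive inversion census at dimension 2
  emb <- embed_rows(x, 2, 1)
  sw <- apply(emb, 1, function(w) sum(w[1] > w[2]))
  p <- as.numeric(table(sw)) / length(sw)
  expect_equal(res$secondary$H2[1], -log(sum(p^2)), tolerance = 1e-12)
})

test_that("GridEn and PhasEn partition their planes consistently", {
  set.seed(308)
  x <- rnorm(300)
  g <- griden(x, m = 4)
  expect_equal(sum(g$secondary$census), length(x) - 1)
  expect_equal(g$secondary$gdr, sum(g$secondary$census > 0) / 16)
  p <- phasen(x, K = 6)
  expect_length(p$secondary$sector_mass, 6)
  expect_true(p$primary >= 0 && p$primary <= 1)
  expect_warning(phasen(rep(1, 30)), "degenerate")
})

test_that("the base registry exposes exactly the 18 estimators and validates input", {
  expect_length(base_estimators(), 18)
  expect_setequal(base_estimators(),
                  c("ApEn", "AttnEn", "BubbEn", "CondEn", "CoSiEn",
                    "DispEn", "DistEn", "EnofEn", "FuzzEn", "GridEn",
                    "IncrEn", "K2En", "PermEn", "PhasEn", "SampEn",
                    "SlopEn", "SpecEn", "SyDyEn"))
  err <- tryCatch(base_entropy("NoSuchEn", rnorm(50)),
                  error = conditionMessage)
  for (nm in base_estimators()) expect_match(err, nm, fixed = TRUE)
  expect_error(base_entropy("SampEn", rnorm(50), bogus = 1), "invalid")
})

test_that("every registry estimator returns a finite non-negative primary on noise", {
  set.seed(309)
  x <- rnorm(500)
  for (nm in base_estimators()) {
    res <- base_entropy(nm, x)
    v <- res$primary[length(res$primary)]
    expect_true(is.finite(v), info = nm)
    expect_gte(v, -1e-12)
    expect_true(length(res$params) >= 1, info = nm)
  }
})
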