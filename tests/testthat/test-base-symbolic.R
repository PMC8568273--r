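# Symbolic estimators: permutation variants, dispersion, slope, increment,
# symbolic-dynamic and corrected conditional entropy.

test_that("PermEn census equals exhaustive pattern enumeration", {
  set.seed(201)
  for (i in 1:10) {
    x <- rnorm(50)
    res <- permen(x, m = 3)
    expect_equal(sort(as.numeric(res$secondary$census), decreasing = TRUE),
                 sort(as.numeric(oracle_perm_census(x, 3, 1)),
                      decreasing = TRUE))
    expect_equal(res$primary[length(res$primary)],
                 shannon_nats(oracle_perm_census(x, 3, 1)),
                 tolerance = 1e-12)
  }
})

test_that("PermEn hits its normalisation extremes", {
  ramp <- seq_len(50)
  res <- permen(ramp, m = 3)
  expect_equal(res$primary, rep(0, 2))
  expect_equal(res$secondary$normalised, rep(0, 2))
  # a sequence realising all m! = 2 patterns equally at m = 2
  alt <- rep(c(1, 2), 25)
  res2 <- permen(alt[-50], m = 2)
  expect_equal(res2$secondary$normalised, 1, tolerance = 0.05)
})

test_that("PermEn of white noise exceeds PermEn of a sinusoid", {
  set.seed(202)
  wins <- vapply(1:25, function(i) {
    noise <- permen(rnorm(400), m = 3)$primary[2]
    tone <- permen(sin(2 * pi * 4 * (1:400) / 400) +
                     rnorm(400, sd = 1e-6), m = 3)$primary[2]
    noise > tone
  }, logical(1))
  expect_true(all(wins))
})

test_that("PermEn variants respond to amplitude as documented", {
  set.seed(203)
  x <- rnorm(100)
  # classic/modified are offset- and scale-pattern invariants
  expect_equal(permen(x, m = 3)$primary,
               permen(x + 10, m = 3)$primary, tolerance = 1e-12)
  expect_equal(permen(x, m = 3, variant = "modified")$primary,
               permen(x + 10, m = 3, variant = "modified")$primary,
               tolerance = 1e-12)
  # weighted is offset invariant (variance weights), amplitude-aware not
  expect_equal(permen(x, m = 3, variant = "weighted")$primary,
               permen(x + 10, m = 3, variant = "weighted")$primary,
               tolerance = 1e-12)
  aa <- permen(x, m = 3, variant = "amplitude-aware")$primary
  aa_shift <- permen(x + 10, m = 3, variant = "amplitude-aware")$primary
  expect_false(isTRUE(all.equal(aa, aa_shift, tolerance = 1e-6)))
  # every variant yields normalised values in [0, 1]
  for (v in c("classic", "edge", "weighted", "amplitude-aware", "modified",
              "fine-grained", "uniform-quantization")) {
    nn <- permen(x, m = 3, variant = v)$secondary$normalised
    expect_true(all(nn >= 0 & nn <= 1 + 1e-12), info = v)
  }
})

test_that("DispEn census matches a hand enumeration and RDE behaves", {
  set.seed(204)
  x <- rnorm(40)
  res <- dispen(x, m = 2, c = 2)
  sym <- ncdf_symbolise(x, 2)
  pats <- paste(sym[-length(sym)], sym[-1], sep = ".")
  expect_equal(res$primary, shannon_nats(table(pats)), tolerance = 1e-12)
  expect_equal(res$secondary$n_patterns, length(unique(pats)))
  # constant series: single degenerate pattern
  expect_equal(dispen(rep(2, 30))$primary, 0)
  # uniform pattern distribution gives RDE = 0
  sym_cycle <- rep(c(1, 1, 2, 2), 250)  # patterns 1.1,1.2,2.2,2.1 equally
  res2 <- dispen(sym_cycle, m = 2, c = 2)
  # NCDF of a two-valued series maps to two classes; all 4 patterns equal
  expect_lt(res2$secondary$rde, 1e-4)
  # normalised DispEn bounded in [0, 1]
  for (i in 1:20) {
    v <- dispen(rnorm(100), normalise = TRUE)$primary
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("SlopEn and IncrEn collapse to zero on constant input and stay in range", {
  expect_equal(slopen(rep(1, 30))$primary, 0)
  expect_equal(incren(rep(1, 30))$primary, 0)
  set.seed(205)
  for (i in 1:10) {
    x <- rnorm(150)
    expect_true(slopen(x)$primary >= 0 && slopen(x)$primary <= 1)
    v <- incren(x, normalise = TRUE)$primary
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("SyDyEn symbolises by quantiles and normalises into [0, 1]", {
  expect_equal(sydyen(rep(4, 30))$primary, 0)
  set.seed(206)
  for (i in 1:10) {
    v <- sydyen(rnorm(200))$primary
    expect_true(v >= 0 && v <= 1)
  }
  # near-uniform symbol usage for a continuous series (MEP property)
  x <- rnorm(3000)
  res <- sydyen(x, m = 1, c = 4, normalise = FALSE)
  expect_gt(res$primary, 0.95 * log(16))
})

test_that("CondEn correction terms follow the word census", {
  set.seed(207)
  x <- rnorm(80)
  res <- conden(x, m = 3)
  expect_length(res$primary, 3)
  expect_equal(res$primary[1], res$secondary$H[1])
  # corrected value = CE + perc * H1, recomputed by hand at k = 2
  H <- res$secondary$H; perc <- res$secondary$singleton_fraction
  expect_equal(res$primary[2], H[2] - H[1] + perc[2] * H[1],
               tolerance = 1e-12)
  # normalised variant divides by H1
  resn <- conden(x, m = 3, normalise = TRUE)
  expect_equal(resn$primary, res$primary / H[1], tolerance = 1e-12)
})
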