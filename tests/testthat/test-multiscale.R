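# Multiscale engines: specs, graining, drivers, hierarchical identities.

test_that("make_spec validates names and parameters and freezes them", {
  sp <- make_spec("SampEn")
  expect_s3_class(sp, "ms_spec")
  expect_identical(sp$family, "base")
  expect_error(make_spec("NoSuchEn"), "valid names")
  expect_error(make_spec("SampEn", list(bogus = 2)), "invalid parameter")
  # frozen params reach every scale's call unchanged (params audit)
  set.seed(501)
  x <- rnorm(300)
  sp2 <- make_spec("SampEn", list(r = 0.33, m = 3L))
  cur <- msen(x, sp2, 2)
  g2 <- coarse_grain(x, 2)
  expect_equal(cur$values[2], sampen(g2, m = 3L, r = 0.33)$primary[4])
})

test_that("coarse_grain implements the three procedures", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_identical(coarse_grain(x, 1), x)
  expect_identical(coarse_grain(x, 1, "modified"), x)
  expect_identical(coarse_grain(x, 1, "generalized"), x)
  expect_equal(coarse_grain(x, 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(x, 2, "modified"),
               c(1.5, 2.5, 3.5, 4.5, 5.5))
  expect_equal(coarse_grain(rep(7, 20), 4, "generalized"), rep(0, 5))
  expect_error(coarse_grain(x, 7), "exceeds")
  # white-noise SD shrinks roughly as 1/sqrt(s)
  set.seed(502)
  ratio <- mean(vapply(1:25, function(i) {
    z <- rnorm(4000)
    sd(coarse_grain(z, 4)) / sd(z)
  }, numeric(1)))
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("scale-1 equivalence holds for every multiscale driver", {
  set.seed(503)
  x <- rnorm(400)
  for (nm in c("SampEn", "PermEn", "DispEn", "FuzzEn")) {
    sp <- make_spec(nm)
    base_val <- {
      res <- base_entropy(nm, x)
      res$primary[length(res$primary)]
    }
    expect_equal(msen(x, sp, 1)$values[1], base_val, info = nm)
    expect_equal(cmsen(x, sp, 1)$values[1], base_val, info = nm)
    expect_equal(rmsen(x, sp, 1)$values[1], base_val, info = nm)
    expect_equal(hmsen(x, sp, 0)$nodes$value[1], base_val, info = nm)
  }
})

test_that("complexity index equals the sum of the curve", {
  set.seed(504)
  x <- rnorm(500)
  cur <- msen(x, make_spec("PermEn"), 4)
  expect_identical(cur$complexity_index, sum(cur$values))
})

test_that("white-noise multiscale SampEn decreases with scale", {
  set.seed(505)
  drops <- vapply(1:25, function(i) {
    cur <- msen(rnorm(2000), make_spec("SampEn"), 4)
    cur$values[1] - cur$values[4]
  }, numeric(1))
  expect_gt(mean(drops > 0), 0.9)
})

test_that("composite averaging equals the manual offset oracle", {
  set.seed(506)
  x <- rnorm(240)
  sp <- make_spec("SampEn", list(r = 0.25))
  cur <- cmsen(x, sp, 2)
  g0 <- coarse_grain(x, 2)
  g1 <- coarse_grain(x[-1], 2)
  manual <- mean(c(sampen(g0, r = 0.25)$primary[3],
                   sampen(g1, r = 0.25)$primary[3]))
  expect_equal(cur$values[2], manual, tolerance = 1e-12)
})

test_that("refined-composite pools match counts before the log", {
  set.seed(507)
  x <- rnorm(240)
  sp <- make_spec("SampEn", list(r = 0.3))
  cur <- cmsen(x, sp, 2, refined = TRUE)
  a <- sampen(coarse_grain(x, 2), r = 0.3)$secondary
  b <- sampen(coarse_grain(x[-1], 2), r = 0.3)$secondary
  expect_equal(cur$values[2],
               -log((a$A[3] + b$A[3]) / (a$B[3] + b$B[3])),
               tolerance = 1e-12)
  expect_error(cmsen(x, make_spec("PermEn"), 2, refined = TRUE),
               "match counts")
})

test_that("refined driver filters, decimates and recomputes the radius", {
  set.seed(508)
  # coloured signal: low-pass removes energy
  x <- as.numeric(stats::filter(rnorm(2000), rep(1, 8), "convolution",
                                sides = 1)[8:2000])
  bf <- signal::butter(6, 0.5 / 3, "low")
  f <- signal::filtfilt(bf, x)
  expect_lt(sd(f), sd(x))
  dec <- f[seq(1, length(f), by = 3)]
  cur <- rmsen(x, make_spec("SampEn"), 3)
  expect_equal(cur$values[3], sampen(dec, r = 0.2 * sd(dec))$primary[3],
               tolerance = 1e-12)
})

test_that("hierarchical decomposition is lossless with the right node count", {
  set.seed(509)
  x <- rnorm(256)
  tr <- hmsen(x, make_spec("SampEn"), 2)
  expect_identical(nrow(tr$nodes), 7L)
  # low + high reconstruct the parent pairs exactly
  for (k in 1:3) {
    parent <- tr$series[[k]]
    lo <- tr$series[[2 * k]]; hi <- tr$series[[2 * k + 1]]
    kk <- length(lo)
    expect_equal(lo + hi, parent[2 * seq_len(kk) - 1], tolerance = 1e-12)
    expect_equal(lo - hi, parent[2 * seq_len(kk)], tolerance = 1e-12)
  }
  expect_error(hmsen(rnorm(50), make_spec("SampEn"), 4), "too short")
})

test_that("drivers demand a spec and report under-length scales as missing", {
  set.seed(510)
  x <- rnorm(70)
  expect_error(msen(x, "SampEn", 2), "ms_spec")
  expect_warning(cur <- msen(x, make_spec("PermEn"), 8), "missing")
  expect_true(is.na(cur$values[8]))
  expect_false(anyNA(cur$values[1:7]))
  expect_identical(length(cur$values), 8L)
})
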