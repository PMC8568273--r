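# Cross-entropy estimators: oracles, symmetry, reductions on identical
# input, registry contract.

test_that("XSampEn equals the exhaustive cross-pair oracle", {
  set.seed(401)
  for (i in 1:15) {
    n <- sample(15:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- 0.2 * sd(c(x, y))
    expect_equal(suppressWarnings(xsampen(x, y, r = r))$primary,
                 oracle_xsampen(x, y, 2, 1, r), tolerance = 1e-12)
  }
})

test_that("symmetric cross estimators satisfy f(x, y) = f(y, x)", {
  set.seed(402)
  for (i in 1:25) {
    x <- rnorm(60); y <- rnorm(60)
    expect_equal(xsampen(x, y)$primary, xsampen(y, x)$primary,
                 tolerance = 1e-12)
    expect_equal(xdisten(x, y)$primary, xdisten(y, x)$primary,
                 tolerance = 1e-12)
    expect_equal(xspecen(x, y)$primary, xspecen(y, x)$primary,
                 tolerance = 1e-12)
  }
})

test_that("XSampEn(x, x) equals SampEn with self-matches retained", {
  set.seed(403)
  for (i in 1:5) {
    n <- 20
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    got <- xsampen(x, x, r = r)$primary
    # oracle: within-series pair counts including self-pairs
    m <- 2
    want <- numeric(m + 1)
    for (k in 0:m) {
      nu <- n - k
      count_self <- function(emb, nuse) {
        cnt <- 0
        for (a in seq_len(nuse)) for (b in seq_len(nuse))
          if (cheb(emb[a, , drop = TRUE], emb[b, , drop = TRUE]) <= r)
            cnt <- cnt + 1
        cnt
      }
      B <- if (k == 0) n * n else
        count_self(embed_rows(x, k, 1), nu)
      A <- count_self(embed_rows(x, k + 1, 1),
                      nrow(embed_rows(x, k + 1, 1)))
      want[k + 1] <- -log(A / B)
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("XApEn is directional and swaps with its arguments", {
  set.seed(404)
  x <- rnorm(60); y <- rnorm(60)
  r <- 0.3 * sd(c(x, y))
  a <- suppressWarnings(xapen(x, y, r = r))
  b <- suppressWarnings(xapen(y, x, r = r))
  expect_match(a$params$direction, "templates from x")
  # the swapped call computes the reverse direction by contract
  expect_equal(suppressWarnings(xapen(y, x, r = r))$primary, b$primary)
  # brute-force oracle at small n
  n <- 18
  x2 <- rnorm(n); y2 <- rnorm(n); r2 <- 0.25 * sd(c(x2, y2))
  phi <- numeric(3)
  for (k in 1:3) {
    ex <- embed_rows(x2, k, 1); ey <- embed_rows(y2, k, 1)
    ci <- vapply(seq_len(nrow(ex)), function(a)
      sum(vapply(seq_len(nrow(ey)), function(b)
        cheb(ex[a, ], ey[b, ]) <= r2, logical(1))) / nrow(ey), numeric(1))
    phi[k] <- mean(log(ci))
  }
  got <- suppressWarnings(xapen(x2, y2, r = r2))$primary
  expect_equal(got, c(0, phi[1:2]) - phi, tolerance = 1e-12)
})

test_that("XPermEn stays within its ordinal bounds and detects coupling", {
  set.seed(405)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    v <- xpermen(x, y)$primary
    expect_gte(v, -1e-12)
    expect_lte(v, log(factorial(3)) + 1e-12)
    # direct enumeration oracle over aligned windows
    ex <- embed_rows(x, 3, 1); ey <- embed_rows(y, 3, 1)
    px <- apply(ex, 1, function(w) paste(order(w), collapse = "."))
    py <- apply(ey, 1, function(w) paste(order(w), collapse = "."))
    want <- shannon_nats(table(paste(px, py))) - shannon_nats(table(px))
    expect_equal(v, want, tolerance = 1e-12)
  }
  set.seed(406)
  x <- rnorm(200)
  expect_equal(xpermen(x, x)$primary, 0, tolerance = 1e-12)
})

test_that("XFuzzEn and XK2En reduce correctly and match oracles", {
  expect_equal(xfuzzen(rep(1, 30), rep(1, 30), r = 0.2)$primary, c(0, 0))
  set.seed(407)
  n <- 20
  x <- rnorm(n); y <- rnorm(n)
  r <- 0.3 * sd(c(x, y))
  # cross correlation sums against a double loop
  res <- xk2en(x, y, r = r)
  for (k in 1:3) {
    ex <- embed_rows(x, k, 1); ey <- embed_rows(y, k, 1)
    cnt <- 0
    for (a in seq_len(nrow(ex))) for (b in seq_len(nrow(ey)))
      if (eucl(ex[a, ], ey[b, ]) <= r) cnt <- cnt + 1
    expect_equal(res$secondary$correlation_sums[k],
                 cnt / (nrow(ex) * nrow(ey)), tolerance = 1e-12)
  }
  expect_true(isTRUE(res$params$unverified))
  expect_true(isTRUE(xspecen(x, y)$params$unverified))
})

test_that("XDistEn is normalised and near its documented level for uniform noise", {
  set.seed(408)
  for (i in 1:20) {
    v <- xdisten(runif(200), runif(200))$primary
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("the cross registry exposes exactly 8 estimators and guards lengths", {
  expect_length(cross_estimators(), 8)
  expect_setequal(cross_estimators(),
                  c("XApEn", "XCondEn", "XDistEn", "XFuzzEn", "XK2En",
                    "XPermEn", "XSampEn", "XSpecEn"))
  expect_error(cross_entropy_fn("NoSuchEn", rnorm(20), rnorm(20)),
               "valid names")
  expect_error(xsampen(rnorm(30), rnorm(40)), "lengths differ")
  expect_no_error(suppressWarnings(
    xsampen(rnorm(30), rnorm(40), allow_unequal = TRUE, r = 0.5)))
})
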