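# Synthetic fixture generators: reproducibility, stated moments, system
# trajectories, chirp frequency law.

test_that("fixtures are reproducible from (name, seed) and demand seeds", {
  for (nm in c("gaussian", "uniform2", "randintegers", "gaussian_Mat")) {
    a <- generate_fixture(nm, seed = 7)
    b <- generate_fixture(nm, seed = 7)
    expect_identical(a, b, info = nm)
    expect_error(generate_fixture(nm), "seed", info = nm)
  }
  # deterministic fixtures need no seed
  expect_identical(generate_fixture("chirp"), generate_fixture("chirp"))
  expect_identical(generate_fixture("lorenz"), generate_fixture("lorenz"))
  expect_error(generate_fixture("nope", seed = 1), "valid names")
})

test_that("gaussian fixture has the stated moments", {
  set.seed(NULL)
  stats <- vapply(1:25, function(s) {
    x <- generate_fixture("gaussian", seed = s)
    c(mean(x), sd(x))
  }, numeric(2))
  expect_true(all(abs(stats[1, ]) < 4 / sqrt(5000)))
  expect_equal(mean(stats[2, ]), 1, tolerance = 0.03)
  expect_identical(length(generate_fixture("gaussian", seed = 1)), 5000L)
})

test_that("uniform2 members are independent uniforms of length 4096", {
  cors <- vapply(1:25, function(s) {
    u <- generate_fixture("uniform2", seed = s)
    cor(u[, 1], u[, 2])
  }, numeric(1))
  expect_true(all(abs(cors) < 0.05))
  u <- generate_fixture("uniform2", seed = 3)
  expect_identical(dim(u), c(4096L, 2L))
  expect_true(all(u >= 0 & u <= 1))
})

test_that("lorenz and henon trajectories are bounded with stated shapes", {
  lor <- generate_fixture("lorenz")
  expect_identical(dim(lor), c(5917L, 3L))
  expect_true(all(is.finite(lor)))
  expect_lt(max(abs(lor)), 60)  # attractor stays on its bounded set
  hen <- generate_fixture("henon")
  expect_identical(dim(hen), c(5000L, 2L))
  expect_lt(max(abs(hen)), 2)
  spec <- attr(lor, "fixture_spec")
  expect_equal(spec$params$dt, 0.01)
  expect_identical(spec$params$integrator, "rk4")
})

test_that("chirp sweeps linearly from f0 to f1 at t1", {
  ch <- generate_fixture("chirp")
  expect_identical(length(ch), 5000L)
  expect_equal(ch[1], 1)  # zero phase
  # instantaneous frequency by phase slope of the analytic law:
  # f(t) = f0 + (f1 - f0) t / t1; estimate near t = 4000 by zero spacing
  seg <- ch[3900:4100]
  zc <- which(diff(sign(seg)) != 0)
  est_f <- 1 / (2 * mean(diff(zc)))
  expect_lt(abs(est_f - 0.025), 0.002)
  # and near t = 0 the frequency is about f0
  seg0 <- ch[1:400]
  zc0 <- which(diff(sign(seg0)) != 0)
  expect_lt(abs(1 / (2 * mean(diff(zc0))) - 0.0107), 0.002)
})

test_that("matrix fixtures have the documented geometry", {
  g <- generate_fixture("gaussian_Mat", seed = 2)
  expect_identical(dim(g), c(60L, 120L))
  mb <- generate_fixture("mandelbrot_Mat")
  expect_identical(dim(mb), c(60L, 120L))
  expect_true(all(mb >= 1 & mb <= 100))
  expect_gt(length(unique(as.vector(mb))), 20)  # non-trivial structure
})

test_that("fetch_hosted validates names and fails cleanly offline", {
  expect_error(fetch_hosted("nope"), "valid names")
  cache <- tempfile("entropics-cache-")
  old <- options(timeout = 2); on.exit(options(old))
  err <- tryCatch(
    fetch_hosted("lorenz", cache_dir = cache,
                 base_url = "https://127.0.0.1:1/none/", timeout = 1),
    error = conditionMessage)
  expect_match(err, "generate_fixture")
})
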