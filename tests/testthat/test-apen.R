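test_that("tolerance is r_factor times the sample SD", {
  x <- c(0, 5, 10, 5, 0)
  expect_equal(tolerance_from_series(x, 0.2), 0.2 * sd(x))
  expect_equal(tolerance_from_series(rep(4, 10)), 0)
  set.seed(3)
  y <- rnorm(40)
  for (a in c(-3, 0.5, 10)) {
    expect_equal(tolerance_from_series(a * y), abs(a) * tolerance_from_series(y),
                 tolerance = 1e-12)
  }
  expect_error(tolerance_from_series(1), class = "kin_error_argument")
  expect_error(tolerance_from_series(rnorm(5), r_factor = 0),
               class = "kin_error_argument")
})

test_that("a constant series has zero entropy and zero-r is flagged", {
  res <- compute_apen(rep(7.5, 60), m = 2, r = 0, tau = 1)
  expect_identical(res$apen, 0)
  res2 <- compute_apen(rep(-1, 60), m = 2, r = 1.5, tau = 1)
  expect_identical(res2$apen, 0)
  expect_warning(compute_apen(rnorm(60), m = 2, r = 0, tau = 1),
                 "exact equality")
})

test_that("entropy is invariant under affine maps when r scales with the data", {
  set.seed(5)
  x <- rnorm(250)
  base <- compute_apen(x, 2, 0.2 * sd(x), 1)$apen
  for (ab in list(c(3, 7), c(-2, 0), c(0.1, -40))) {
    y <- ab[1] * x + ab[2]
    expect_equal(compute_apen(y, 2, 0.2 * sd(y), 1)$apen, base,
                 tolerance = 1e-12)
  }
})

test_that("entropy is non-increasing in the tolerance (match-rich regime)", {
  # at very small r the self-match floor drives ApEn towards 0, so the
  # decrease in r holds from the conventional tolerance range upwards
  set.seed(8)
  x <- rnorm(200)
  grid <- seq(0.5, 2.5, length.out = 10) * sd(x)
  vals <- vapply(grid, function(r) compute_apen(x, 2, r, 1)$apen, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("the compiled kernel equals the plain-R reference", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(60:400, 1)
    m <- sample(1:3, 1)
    tau <- sample(c(1L, 2L, 5L), 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expect_equal(compute_apen(x, m, r, tau)$apen, apen_reference(x, m, r, tau),
                 tolerance = 1e-10)
  }
})

test_that("short series raise the insufficient-embedding error", {
  expect_error(compute_apen(rnorm(20), m = 2, r = 0.5, tau = 10),
               class = "kin_error_insufficient_embedding")
  expect_error(compute_apen(rnorm(11), m = 1, r = 0.5, tau = 2),
               class = "kin_error_insufficient_embedding")
  # boundary: exactly 10 vectors at dimension m+1 is allowed
  expect_s3_class(compute_apen(rnorm(30), m = 2, r = 0.5, tau = 10),
                  "apen_result")
})

test_that("metadata in the result matches the inputs", {
  set.seed(2)
  x <- rnorm(120)
  res <- compute_apen(x, m = 3, r = 0.4, tau = 2)
  expect_identical(res$m, 3L)
  expect_identical(res$tau, 2L)
  expect_identical(res$n, 120L)
  expect_identical(res$m_vectors, 120L - 2L * 2L)
  expect_true(res$apen >= 0)
})

test_that("analyze_series chains delay selection, tolerance and entropy", {
  s <- simulate_joint_series(signal_params(), 30, seed = 7)
  res <- analyze_series(s)
  expect_true(res$tau$found)
  expect_equal(res$r, 0.2 * sd(s$values))
  expect_equal(res$mean_angle, mean(s$values))
  direct <- compute_apen(s$values, m = 2, r = res$r, tau = res$tau$tau)
  expect_identical(res$apen$apen, direct$apen)
  # determinism on repeated calls
  res2 <- analyze_series(s$values)
  expect_identical(res$apen$apen, res2$apen$apen)
  expect_error(analyze_series(rep(1, 100)), class = "kin_error_constant_series")
})

test_that("noisier generators yield higher entropy (median over replicates)", {
  med_apen <- function(sigma) {
    vals <- vapply(1:10, function(i) {
      s <- simulate_joint_series(signal_params(noise_sd = sigma), 30,
                                 seed = 900 + i)
      analyze_series(s)$apen$apen
    }, numeric(1))
    median(vals)
  }
  meds <- vapply(c(0.2, 2.0), med_apen, numeric(1))
  expect_true(meds[1] < meds[2])
})
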