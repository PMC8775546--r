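test_that("autocorrelation matches the shared-denominator definition", {
  set.seed(11)
  for (n in c(8L, 37L, 200L)) {
    x <- rnorm(n) + seq_len(n) * 0.05
    p <- compute_acf(x, max_shift = n - 1L)
    expect_identical(p$shifts, 0L:(n - 1L))
    expect_equal(p$acf[1], 1)
    for (k in c(1L, 2L, n %/% 2L, n - 1L)) {
      expect_equal(p$acf[k + 1L], acf_oracle(x, k), tolerance = 1e-12)
    }
    expect_true(all(abs(p$acf) <= 1 + 1e-12))
  }
})

test_that("alternating series has acf(1) = -(n-1)/n", {
  for (n in c(4L, 10L, 50L)) {
    x <- rep(c(1, -1), n / 2)
    p <- compute_acf(x, max_shift = 2L)
    expect_equal(p$acf[2], -(n - 1) / n, tolerance = 1e-12)
  }
})

test_that("constant and malformed inputs raise classed errors", {
  expect_error(compute_acf(rep(3, 50)), class = "kin_error_constant_series")
  expect_error(compute_acf(rnorm(20), max_shift = 0), class = "kin_error_argument")
  expect_error(compute_acf(rnorm(20), max_shift = 20), class = "kin_error_argument")
  expect_error(compute_acf(c(1, NA, 2)), class = "kin_error_argument")
})

test_that("tau is the first shift whose acf magnitude clears the threshold", {
  prof <- structure(list(shifts = 0:4, acf = c(1, 0.5, 0.09, -0.3, 0.01),
                         n_source = 100L), class = "acf_profile")
  est <- estimate_tau(prof, threshold = 0.1)
  expect_true(est$found)
  expect_identical(est$tau, 2L)
  expect_equal(est$acf_at_tau, 0.09)

  none <- estimate_tau(structure(list(shifts = 0:3, acf = c(1, 0.9, 0.5, 0.2),
                                      n_source = 50L), class = "acf_profile"),
                       threshold = 0.1)
  expect_false(none$found)
  expect_true(is.na(none$tau))

  # signed mode: a strongly negative acf qualifies
  neg <- structure(list(shifts = 0:2, acf = c(1, -0.5, 0.05),
                        n_source = 50L), class = "acf_profile")
  expect_identical(estimate_tau(neg, 0.1, mode = "absolute")$tau, 2L)
  expect_identical(estimate_tau(neg, 0.1, mode = "signed")$tau, 1L)
})

test_that("tau search is monotone in the threshold", {
  set.seed(21)
  for (rep_i in 1:20) {
    x <- as.numeric(stats::filter(rnorm(300), 0.8, method = "recursive"))
    prof <- compute_acf(x, 100)
    taus <- vapply(c(0.4, 0.2, 0.1, 0.05), function(th) {
      est <- estimate_tau(prof, th)
      if (est$found) est$tau else NA_integer_
    }, integer(1))
    found <- !is.na(taus)
    expect_true(all(diff(taus[found]) >= 0))
  }
})

test_that("iid series select tau = 1 at n = 10000", {
  hits <- 0L
  for (i in 1:25) {
    set.seed(500 + i)
    x <- rnorm(10000)
    est <- estimate_tau(compute_acf(x, max_shift = 50L), 0.1)
    if (est$found && est$tau == 1L) hits <- hits + 1L
  }
  expect_identical(hits, 25L)
})
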