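test_that("the generator is deterministic and RNG-clean", {
  p <- signal_params()
  a <- simulate_joint_series(p, 10, seed = 5)
  b <- simulate_joint_series(p, 10, seed = 5)
  expect_identical(a$values, b$values)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_joint_series(p, 5, seed = 1))
  after <- rnorm(1)
  expect_identical(before, after)  # caller RNG state untouched
})

test_that("the AR(1) irregularity has the requested stationary SD", {
  # isolate the noise: zero-amplitude harmonics, zero mean
  p <- signal_params(harmonics = data.frame(multiple = 1, amplitude = 0,
                                            phase = 0),
                     mean_angle = 0, noise_sd = 2, ar_coeff = 0.3)
  sds <- vapply(1:20, function(i) {
    sd(simulate_joint_series(p, 100, seed = 200 + i)$values)
  }, numeric(1))
  expect_lt(abs(mean(sds) - 2) / 2, 0.05)
})

test_that("a noiseless, jitter-free signal is exactly periodic with low entropy", {
  p <- signal_params(noise_sd = 0, phase_jitter_sd = 0)
  s <- simulate_joint_series(p, 30, seed = 1)
  # period 1/0.9 s is not an integer number of samples, but the harmonic sum
  # is an exact function of time: check against direct evaluation
  tt <- (seq_len(s$n) - 1L) / s$fs
  direct <- p$mean_angle +
    p$harmonics$amplitude[1] * sin(2 * pi * 0.9 * tt + p$harmonics$phase[1]) +
    p$harmonics$amplitude[2] * sin(2 * pi * 2 * 0.9 * tt + p$harmonics$phase[2])
  expect_equal(s$values, direct, tolerance = 1e-12)
  res <- analyze_series(s)
  expect_lt(res$apen$apen, 0.3)  # bound frozen from an oracle run at defaults
})

test_that("median entropy is nondecreasing in the noise level", {
  meds <- vapply(c(0.2, 0.5, 1, 2), function(sigma) {
    vals <- vapply(1:10, function(i) {
      s <- simulate_joint_series(signal_params(noise_sd = sigma), 30,
                                 seed = 3000 + i)
      analyze_series(s)$apen$apen
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("cohort simulation honours the spec shape and asymmetry", {
  spec <- cohort_spec(n_pd = 3L, n_oa = 2L, dances = c("tango", "line"),
                      recordings_per_dance = 2L,
                      duration_range_min = c(0.25, 0.5),
                      channels = "knee_flexion", asymmetry_gamma = 0.25,
                      seed = 7L)
  sim <- simulate_cohort(spec)
  expect_identical(nrow(sim$manifest), 5L * 2L * 2L)
  expect_identical(sum(sim$manifest$group == "PD"), 3L * 2L * 2L)
  durs <- vapply(sim$cohort$recordings, function(r) r$duration_min, numeric(1))
  expect_true(all(durs >= 0.25 & durs <= 0.5))
  # asymmetric PD: lower entropy on the affected left side
  per <- analyze_cohort(sim$cohort, pipeline_config(channels = "knee_flexion"))
  pd <- per[per$group == "PD" & per$status == "ok", ]
  expect_lt(mean(pd$apen[pd$side == "left"]), mean(pd$apen[pd$side == "right"]))
  # symmetric generation: identical parameters per side (series still differ)
  spec_sym <- cohort_spec(n_pd = 2L, n_oa = 0L, dances = "tango",
                          recordings_per_dance = 1L,
                          duration_range_min = c(0.25, 0.25),
                          channels = "knee_flexion", asymmetry_gamma = 1,
                          seed = 8L)
  sim_sym <- simulate_cohort(spec_sym)
  rec <- sim_sym$cohort$recordings[[1]]
  l <- rec$channels[["left_knee_flexion"]]$values
  r <- rec$channels[["right_knee_flexion"]]$values
  expect_false(identical(l, r))
  expect_lt(abs(sd(l) - sd(r)) / sd(l), 0.25)
})

test_that("simulated cohorts round-trip through the I/O layer", {
  d <- withr::local_tempdir()
  spec <- cohort_spec(n_pd = 1L, n_oa = 1L, dances = "tango",
                      recordings_per_dance = 1L,
                      duration_range_min = c(0.2, 0.2),
                      channels = c("knee_flexion", "hip_abduction"), seed = 11L)
  sim <- simulate_cohort(spec, out_dir = d)
  coh <- load_cohort(sim$manifest_path)
  expect_length(coh$recordings, 2L)
  for (id in names(coh$recordings)) {
    mem <- sim$cohort$recordings[[id]]
    disk <- coh$recordings[[id]]
    for (cn in names(mem$channels)) {
      expect_identical(disk$channels[[cn]]$values, mem$channels[[cn]]$values)
    }
  }
})

test_that("fixtures are registered, pinned and reproducible", {
  expect_error(make_fixture("nope"), "minimal_symmetric")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_fixture("minimal_symmetric", d1)
  f2 <- make_fixture("minimal_symmetric", d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  rep <- run_pipeline(f1$manifest_path, pipeline_config())
  expect_true(all(rep$per_series$status == "ok"))
})
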