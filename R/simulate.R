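#' Parameters of a simulated quasi-periodic joint-angle signal
#'
#' The generator is a harmonic oscillation around a mean posture with two
#' irregularity sources: additive AR(1) noise and (optionally) cumulative
#' per-cycle phase jitter,
#' \deqn{\theta(t) = \mu + \sum_h A_h \sin(2\pi h f t + \phi_h + J(t)) + \varepsilon(t),}
#' where J is a random walk advancing once per movement cycle and
#' \eqn{\varepsilon} is AR(1) with stationary SD `noise_sd`. It reproduces
#' the statistical structure the entropy analysis relies on — a nontrivial
#' autocorrelation delay and tunable regularity — without being a
#' biomechanical model.
#'
#' @param base_freq fundamental (step) frequency in Hz; default 0.9, a
#'   typical unhurried dance-step rate.
#' @param harmonics data frame with columns `multiple`, `amplitude`
#'   (degrees) and `phase` (radians); one row per harmonic.
#' @param mean_angle mean joint angle in degrees.
#' @param noise_sd stationary SD of the AR(1) irregularity in degrees
#'   (the regularity knob); default 2.
#' @param ar_coeff AR(1) coefficient in [0, 1); default 0.3.
#' @param phase_jitter_sd SD of the per-cycle phase-jitter increment in
#'   radians; default 0 (no timing drift).
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(base_freq = 0.9,
                          harmonics = data.frame(multiple = c(1, 2),
                                                 amplitude = c(20, 6),
                                                 phase = c(0, 0.8)),
                          mean_angle = 30, noise_sd = 2, ar_coeff = 0.3,
                          phase_jitter_sd = 0) {
  if (!is.numeric(base_freq) || base_freq <= 0) {
    kin_abort("kin_error_argument", "base_freq must be > 0")
  }
  if (!is.data.frame(harmonics) ||
      !all(c("multiple", "amplitude", "phase") %in% names(harmonics)) ||
      any(harmonics$amplitude < 0)) {
    kin_abort("kin_error_argument",
              "harmonics must have columns multiple, amplitude (>= 0), phase")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    kin_abort("kin_error_argument", "noise_sd must be >= 0")
  }
  if (!is.numeric(ar_coeff) || ar_coeff < 0 || ar_coeff >= 1) {
    kin_abort("kin_error_argument", "ar_coeff must be in [0, 1)")
  }
  if (!is.numeric(phase_jitter_sd) || phase_jitter_sd < 0) {
    kin_abort("kin_error_argument", "phase_jitter_sd must be >= 0")
  }
  structure(
    list(base_freq = base_freq, harmonics = harmonics,
         mean_angle = mean_angle, noise_sd = noise_sd, ar_coeff = ar_coeff,
         phase_jitter_sd = phase_jitter_sd),
    class = "signal_params"
  )
}

# Channel-typical posture and range-of-motion defaults (degrees) for the
# joint measures captured by a lower/upper-limb IMU set during dance.
#' Default signal parameters for a joint measure
#' @param joint,measure channel identity (see [joint_series()]).
#' @param ... overrides passed to [signal_params()].
#' @return A `signal_params` object.
#' @export
default_signal_params <- function(joint, measure, ...) {
  key <- paste(joint, measure, sep = "_")
  base <- switch(key,
    knee_flexion = list(mean_angle = 30, amp = c(25, 7)),
    hip_flexion = list(mean_angle = 15, amp = c(15, 5)),
    hip_abduction = list(mean_angle = 5, amp = c(8, 2)),
    hip_rotation = list(mean_angle = 0, amp = c(6, 2)),
    elbow_flexion = list(mean_angle = 45, amp = c(10, 3)),
    kin_abort("kin_error_argument", sprintf("unknown channel: %s", key))
  )
  defaults <- list(
    mean_angle = base$mean_angle,
    harmonics = data.frame(multiple = c(1, 2), amplitude = base$amp,
                           phase = c(0, 0.8))
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(signal_params, args)
}

#' Simulate one joint-angle series
#'
#' Deterministic given `seed`: the same call always returns the same
#' samples, and the caller's RNG state is left untouched.
#'
#' @param params a [signal_params()].
#' @param duration_s recording duration in seconds.
#' @param fs sampling frequency in Hz; default 100.
#' @param seed integer seed.
#' @param joint,measure,side,recording_id channel metadata (see
#'   [joint_series()]).
#' @return A [`joint_series`][joint_series].
#' @export
simulate_joint_series <- function(params, duration_s, fs = 100, seed = 1L,
                                  joint = "knee", measure = "flexion",
                                  side = "left",
                                  recording_id = NA_character_) {
  if (!inherits(params, "signal_params")) {
    kin_abort("kin_error_argument", "params must be a signal_params object")
  }
  n <- as.integer(round(duration_s * fs))
  if (n < 2L) kin_abort("kin_error_argument", "duration_s * fs must be >= 2")
  tt <- (seq_len(n) - 1L) / fs
  values <- with_seed(seed, {
    # cumulative per-cycle phase jitter: one random increment per movement
    # cycle, held constant within the cycle
    jit <- numeric(n)
    if (params$phase_jitter_sd > 0) {
      cyc <- floor(params$base_freq * tt)
      incr <- stats::rnorm(max(cyc) + 1L, sd = params$phase_jitter_sd)
      incr[1] <- 0
      jit <- cumsum(incr)[cyc + 1L]
    }
    sig <- rep(params$mean_angle, n)
    for (h in seq_len(nrow(params$harmonics))) {
      sig <- sig + params$harmonics$amplitude[h] *
        sin(2 * pi * params$harmonics$multiple[h] * params$base_freq * tt +
              params$harmonics$phase[h] + jit)
    }
    if (params$noise_sd > 0) {
      innov_sd <- params$noise_sd * sqrt(1 - params$ar_coeff^2)
      eps <- as.numeric(stats::filter(
        stats::rnorm(n, sd = innov_sd), params$ar_coeff,
        method = "recursive",
        init = stats::rnorm(1, sd = params$noise_sd)))
      sig <- sig + eps
    }
    sig
  })
  joint_series(values, fs = fs, joint = joint, measure = measure,
               side = side, recording_id = recording_id)
}

#' Specification of a simulated cohort
#'
#' Defaults emulate the shape of a small community-dance study: 7
#' Parkinson's-like (PD) and 5 older-adult-like (OA) participants, several
#' dance types per participant, recordings of 1-4 minutes at 100 Hz.
#' PD-like participants have the noise SD of the affected side multiplied
#' by `asymmetry_gamma` on all generated channels (reduced irregularity =
#' reduced movement complexity on the more-affected side); `gamma = 1`
#' makes the sides statistically identical.
#'
#' @param n_pd,n_oa participants per group (either may be 0, not both).
#' @param dances dance types each participant records.
#' @param recordings_per_dance recordings per participant and dance.
#' @param duration_range_min recording duration range in minutes,
#'   drawn uniformly; default `c(1, 4)`.
#' @param fs sampling frequency; default 100.
#' @param channels `<joint>_<measure>` names generated for both sides;
#'   default the lower-limb set.
#' @param asymmetry_gamma noise multiplier in (0, 1] for the affected side
#'   of PD-like participants; default 0.25.
#' @param affected_side side receiving the reduction; default `"left"`.
#' @param noise_sd baseline irregularity SD in degrees; default 2.
#' @param phase_jitter_sd per-cycle phase jitter SD; default 0.05 radians
#'   (slight step-timing drift, so recordings are quasi- rather than
#'   strictly periodic).
#' @param seed master seed; all per-recording seeds derive from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 7L, n_oa = 5L,
                        dances = c("tango", "foxtrot", "waltz", "line"),
                        recordings_per_dance = 1L,
                        duration_range_min = c(1, 4), fs = 100,
                        channels = lower_limb_channels(),
                        asymmetry_gamma = 0.25, affected_side = "left",
                        noise_sd = 2, phase_jitter_sd = 0.05, seed = 1L) {
  n_pd <- as.integer(n_pd); n_oa <- as.integer(n_oa)
  if (n_pd < 0L || n_oa < 0L || n_pd + n_oa < 1L) {
    kin_abort("kin_error_argument", "need at least one participant")
  }
  if (!all(dances %in% kin_dances)) {
    kin_abort("kin_error_argument", "unknown dance type")
  }
  if (recordings_per_dance < 1L) {
    kin_abort("kin_error_argument", "recordings_per_dance must be >= 1")
  }
  if (length(duration_range_min) != 2L || any(duration_range_min <= 0) ||
      duration_range_min[1] > duration_range_min[2]) {
    kin_abort("kin_error_argument", "duration_range_min must be c(lo, hi), lo <= hi, > 0")
  }
  if (!is.numeric(asymmetry_gamma) || asymmetry_gamma <= 0 ||
      asymmetry_gamma > 1) {
    kin_abort("kin_error_argument", "asymmetry_gamma must be in (0, 1]")
  }
  affected_side <- match.arg(affected_side, kin_sides)
  structure(
    list(n_pd = n_pd, n_oa = n_oa, dances = dances,
         recordings_per_dance = as.integer(recordings_per_dance),
         duration_range_min = duration_range_min, fs = fs,
         channels = channels, asymmetry_gamma = asymmetry_gamma,
         affected_side = affected_side, noise_sd = noise_sd,
         phase_jitter_sd = phase_jitter_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

derive_seed <- function(master, i, j) {
  as.integer((as.double(master) * 100003 + i * 1009 + j * 7919) %% 2147483629)
}

#' Simulate a whole kinematic cohort
#'
#' Generates every recording of a [cohort_spec()]: for each participant,
#' dance and repetition, one recording with the configured channels on both
#' sides. PD-like participants get `noise_sd * asymmetry_gamma` on the
#' affected side. Durations are drawn uniformly from the spec's range using
#' the master seed; every channel's series uses a sub-seed derived
#' deterministically from the master seed, so the whole cohort is
#' reproducible.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory: when given, recording CSVs and a
#'   `manifest.csv` are written there (the on-disk route exercised by the
#'   I/O layer); when `NULL` the cohort is returned in memory only.
#' @return List with `cohort` (a [`cohort`][cohort]), `manifest` (data
#'   frame) and, when written, `manifest_path`.
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  if (!inherits(spec, "cohort_spec")) {
    kin_abort("kin_error_argument", "spec must be a cohort_spec")
  }
  participants <- rbind(
    if (spec$n_pd > 0L) data.frame(participant_id = sprintf("pd%02d", seq_len(spec$n_pd)),
                                   group = "PD", stringsAsFactors = FALSE),
    if (spec$n_oa > 0L) data.frame(participant_id = sprintf("oa%02d", seq_len(spec$n_oa)),
                                   group = "OA", stringsAsFactors = FALSE)
  )
  grid <- expand.grid(rep = seq_len(spec$recordings_per_dance),
                      dance = spec$dances,
                      idx = seq_len(nrow(participants)),
                      stringsAsFactors = FALSE)
  n_rec <- nrow(grid)
  durations <- with_seed(spec$seed, {
    stats::runif(n_rec, spec$duration_range_min[1], spec$duration_range_min[2])
  })
  recs <- vector("list", n_rec)
  manifest <- data.frame(file = character(n_rec),
                         participant_id = character(n_rec),
                         group = character(n_rec), dance = character(n_rec),
                         recording_id = character(n_rec),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_rec)) {
    p <- participants[grid$idx[i], ]
    rec_id <- sprintf("%s_%s_%d", p$participant_id, grid$dance[i], grid$rep[i])
    channels <- list()
    j <- 0L
    for (jm in spec$channels) {
      joint <- sub("_.*$", "", jm)
      measure <- sub("^.*_", "", jm)
      for (side in kin_sides) {
        j <- j + 1L
        nsd <- spec$noise_sd
        if (p$group == "PD" && side == spec$affected_side) {
          nsd <- nsd * spec$asymmetry_gamma
        }
        params <- default_signal_params(joint, measure, noise_sd = nsd,
                                        phase_jitter_sd = spec$phase_jitter_sd)
        channels[[length(channels) + 1L]] <- simulate_joint_series(
          params, duration_s = durations[i] * 60, fs = spec$fs,
          seed = derive_seed(spec$seed, i, j), joint = joint,
          measure = measure, side = side, recording_id = rec_id)
      }
    }
    recs[[i]] <- recording(rec_id, p$participant_id, p$group,
                           grid$dance[i], channels, fs = spec$fs)
    manifest$file[i] <- paste0(rec_id, ".csv")
    manifest$participant_id[i] <- p$participant_id
    manifest$group[i] <- p$group
    manifest$dance[i] <- grid$dance[i]
    manifest$recording_id[i] <- rec_id
  }
  coh <- cohort(recs)
  out <- list(cohort = coh, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n_rec)) {
      write_recording_csv(recs[[i]], file.path(out_dir, manifest$file[i]))
    }
    out$manifest_path <- file.path(out_dir, "manifest.csv")
    write_manifest_csv(manifest, out$manifest_path)
  }
  out
}

#' Registered pinned fixtures
#'
#' Tiny deterministic datasets for regression tests and demos:
#' \describe{
#'   \item{`minimal_symmetric`}{2 OA-like participants, 1 dance, 30 s
#'     recordings, knee and hip flexion both sides; loads cleanly through
#'     [run_pipeline()].}
#'   \item{`tau_not_found`}{one recording whose knee-flexion channels are a
#'     slow trend: over the restricted autocorrelation window shipped in the
#'     fixture's `config` (`max_shift_fraction = 0.05`) the ACF never drops
#'     below 0.1, exercising the delay-not-found failure path.}
#' }
#'
#' @param name fixture name.
#' @param out_dir directory to write into; default a fresh temp directory.
#' @return List with `dir`, `manifest_path` and `config` (an
#'   [apen_config()] suited to the fixture).
#' @export
make_fixture <- function(name, out_dir = tempfile("kinfix")) {
  fixtures <- c("minimal_symmetric", "tau_not_found")
  if (!name %in% fixtures) {
    kin_abort("kin_error_argument",
              sprintf("unknown fixture '%s'; available: %s", name,
                      paste(fixtures, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (name == "minimal_symmetric") {
    spec <- cohort_spec(n_pd = 0L, n_oa = 2L, dances = "tango",
                        recordings_per_dance = 1L,
                        duration_range_min = c(0.5, 0.5),
                        channels = c("knee_flexion", "hip_flexion"),
                        asymmetry_gamma = 1, seed = 42L)
    sim <- simulate_cohort(spec, out_dir = out_dir)
    return(list(dir = out_dir, manifest_path = sim$manifest_path,
                config = apen_config()))
  }
  # tau_not_found: slow monotone drift plus a faint oscillation keeps the
  # short-window ACF above 0.1 everywhere
  n <- 3000L; fs <- 100
  tt <- (seq_len(n) - 1L) / fs
  drift <- 20 * tt / max(tt) + 0.05 * sin(2 * pi * 0.02 * tt)
  chans <- lapply(kin_sides, function(side) {
    joint_series(drift, fs = fs, joint = "knee", measure = "flexion",
                 side = side, recording_id = "trend_1")
  })
  rec <- recording("trend_1", "p01", "OA", "tango", chans, fs = fs)
  write_recording_csv(rec, file.path(out_dir, "trend_1.csv"))
  manifest <- data.frame(file = "trend_1.csv", participant_id = "p01",
                         group = "OA", dance = "tango",
                         recording_id = "trend_1", stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write_manifest_csv(manifest, manifest_path)
  list(dir = out_dir, manifest_path = manifest_path,
       config = apen_config(max_shift_fraction = 0.05))
}
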