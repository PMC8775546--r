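#' Configuration for single-series entropy analysis
#'
#' Bundles the tunable parameters of the per-series analysis chain:
#' autocorrelation window, delay-selection threshold, pattern length and
#' tolerance factor.
#'
#' @param m pattern length for ApEn; default 2.
#' @param r_factor tolerance as a fraction of the series SD; default 0.2.
#' @param acf_threshold delay qualifies when its autocorrelation magnitude
#'   falls below this bound; default 0.1.
#' @param max_shift_fraction fraction of the series length used as the
#'   largest autocorrelation shift K (default 1, i.e. K = n - 1). Lowering it
#'   trades completeness of the delay search for speed.
#' @param tau_mode `"absolute"` or `"signed"`; see [estimate_tau()].
#' @return An object of class `apen_config`.
#' @export
apen_config <- function(m = 2L, r_factor = 0.2, acf_threshold = 0.1,
                        max_shift_fraction = 1.0,
                        tau_mode = c("absolute", "signed")) {
  tau_mode <- match.arg(tau_mode)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) kin_abort("kin_error_argument", "m must be >= 1")
  if (!is.numeric(r_factor) || r_factor <= 0) {
    kin_abort("kin_error_argument", "r_factor must be > 0")
  }
  if (!is.numeric(acf_threshold) || acf_threshold <= 0 || acf_threshold >= 1) {
    kin_abort("kin_error_argument", "acf_threshold must be in (0, 1)")
  }
  if (!is.numeric(max_shift_fraction) || max_shift_fraction <= 0 ||
      max_shift_fraction > 1) {
    kin_abort("kin_error_argument", "max_shift_fraction must be in (0, 1]")
  }
  structure(
    list(m = m, r_factor = r_factor, acf_threshold = acf_threshold,
         max_shift_fraction = max_shift_fraction, tau_mode = tau_mode),
    class = "apen_config"
  )
}

#' Analyse one joint-angle series: delay, tolerance, entropy, mean angle
#'
#' Chains the per-recording analysis: [compute_acf()] over shifts
#' `1..floor(max_shift_fraction * (n - 1))`, [estimate_tau()] at the
#' configured threshold, [tolerance_from_series()], then [compute_apen()]
#' at the selected delay. Also reports the arithmetic mean of the raw
#' samples (the "mean movement" summary used alongside entropy).
#'
#' Failures are recording-level, not run-level: a constant series, an
#' unfindable delay, or a series too short for the embedding each raise a
#' classed error (`kin_error_constant_series`, `kin_error_tau_not_found`,
#' `kin_error_insufficient_embedding`) which the cohort pipeline converts to
#' a QC entry.
#'
#' @param x numeric vector of samples (or a [`joint_series`][joint_series],
#'   whose samples are used).
#' @param config an [apen_config()].
#' @return List with elements `tau` (a `tau_estimate`), `apen` (an
#'   `apen_result`), `mean_angle`, and `r`.
#' @export
analyze_series <- function(x, config = apen_config()) {
  if (inherits(x, "joint_series")) x <- x$values
  x <- as.numeric(x)
  n <- length(x)
  max_shift <- max(1L, as.integer(floor(config$max_shift_fraction * (n - 1L))))
  profile <- compute_acf(x, max_shift = max_shift)
  tau_est <- estimate_tau(profile, threshold = config$acf_threshold,
                          mode = config$tau_mode)
  if (!tau_est$found) {
    kin_abort("kin_error_tau_not_found",
              sprintf("no shift in 1..%d with qualifying autocorrelation (threshold %.3g)",
                      max_shift, config$acf_threshold))
  }
  r <- tolerance_from_series(x, config$r_factor)
  apen <- compute_apen(x, m = config$m, r = r, tau = tau_est$tau)
  list(tau = tau_est, apen = apen, mean_angle = mean(x), r = r)
}
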