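#' Sample autocorrelation profile of a signal
#'
#' Computes the demeaned, shared-denominator sample autocorrelation
#' \deqn{\hat\rho(k) = \frac{\sum_{t=1}^{n-k}(x_t-\bar x)(x_{t+k}-\bar x)}
#'                         {\sum_{t=1}^{n}(x_t-\bar x)^2}}
#' for shifts \eqn{k = 0, \dots, K}. The shared denominator guarantees
#' \eqn{|\hat\rho(k)| \le 1} and \eqn{\hat\rho(0) = 1}. Shifts are 0-based:
#' shift 0 is the series against itself (some plotting conventions call this
#' "lag 1"; here shift k means a displacement of k samples).
#'
#' @param x numeric vector, all values finite, non-constant.
#' @param max_shift largest shift K to compute, in `1..length(x) - 1`.
#' @return An object of class `acf_profile`: list with `shifts` (integer
#'   vector `0:max_shift`), `acf` (autocorrelation per shift) and `n_source`
#'   (length of `x`).
#' @seealso [estimate_tau()] to pick the embedding delay from the profile.
#' @examples
#' p <- compute_acf(sin(2 * pi * 0.9 * seq(0, 10, by = 0.01)), max_shift = 200)
#' p$acf[1]  # shift 0: exactly 1
#' @export
compute_acf <- function(x, max_shift = length(x) - 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L || !all(is.finite(x))) {
    kin_abort("kin_error_argument", "x must be a finite numeric vector with n >= 2")
  }
  if (var(x) == 0) {
    kin_abort("kin_error_constant_series",
              "constant series: autocorrelation is undefined (zero variance)")
  }
  max_shift <- as.integer(max_shift)
  if (length(max_shift) != 1L || is.na(max_shift) ||
      max_shift < 1L || max_shift > n - 1L) {
    kin_abort("kin_error_argument",
              sprintf("max_shift must be in 1..%d (n - 1), got %s",
                      n - 1L, format(max_shift)))
  }
  # stats::acf with demean = TRUE is exactly the shared-denominator estimator
  rho <- as.numeric(stats::acf(x, lag.max = max_shift, plot = FALSE,
                               demean = TRUE, type = "correlation")$acf)
  rho[1] <- 1  # self-correlation at zero shift is 1 by definition
  structure(
    list(shifts = 0L:max_shift, acf = rho, n_source = n),
    class = "acf_profile"
  )
}

#' @export
print.acf_profile <- function(x, ...) {
  cat(sprintf("<acf_profile> n = %d, shifts 0..%d\n",
              x$n_source, max(x$shifts)))
  k <- which(abs(x$acf[-1]) < 0.1)
  if (length(k)) {
    cat(sprintf("  first shift with |acf| < 0.1: %d (acf = %.4f)\n",
                k[1], x$acf[k[1] + 1L]))
  } else {
    cat("  no shift with |acf| < 0.1 within the computed range\n")
  }
  invisible(x)
}

#' Select the embedding delay (tau) from an autocorrelation profile
#'
#' Returns the smallest positive shift at which the autocorrelation is
#' "closest to zero" in the operational sense of falling below a small
#' threshold: the first shift `k >= 1` with `|acf(k)| < threshold`
#' (`mode = "absolute"`, the default) or `acf(k) < threshold`
#' (`mode = "signed"`). If no shift qualifies within the profile's range the
#' result has `found = FALSE`; callers treat that as a per-recording failure.
#'
#' @param profile an [`acf_profile`][compute_acf].
#' @param threshold qualification bound on the autocorrelation, in (0, 1);
#'   default 0.1.
#' @param mode `"absolute"` (|acf| must be small) or `"signed"` (acf must
#'   drop below `threshold`, so strongly negative values qualify).
#' @return An object of class `tau_estimate`: list with `tau` (integer shift,
#'   `NA` when not found), `acf_at_tau`, `threshold`, `found`.
#' @examples
#' x <- sin(2 * pi * seq(0, 30, by = 0.01)) + rnorm(3001, sd = 0.5)
#' estimate_tau(compute_acf(x, 500))
#' @export
estimate_tau <- function(profile, threshold = 0.1,
                         mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (!inherits(profile, "acf_profile")) {
    kin_abort("kin_error_argument", "profile must be an acf_profile")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    kin_abort("kin_error_argument", "threshold must be in (0, 1)")
  }
  rho <- profile$acf[-1L]  # shifts 1..K
  qualifies <- if (mode == "absolute") abs(rho) < threshold else rho < threshold
  k <- which(qualifies)
  if (length(k) == 0L) {
    out <- list(tau = NA_integer_, acf_at_tau = NA_real_,
                threshold = threshold, found = FALSE)
  } else {
    out <- list(tau = as.integer(k[1L]), acf_at_tau = rho[k[1L]],
                threshold = threshold, found = TRUE)
  }
  structure(out, class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<tau_estimate> tau = %d samples, acf(tau) = %.4f (threshold %.3g)\n",
                x$tau, x$acf_at_tau, x$threshold))
  } else {
    cat(sprintf("<tau_estimate> not found: no shift with qualifying acf (threshold %.3g)\n",
                x$threshold))
  }
  invisible(x)
}
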