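#' Similarity tolerance from a series' spread
#'
#' The match tolerance r used by [compute_apen()] is conventionally a fixed
#' fraction of the series' variability: `r_factor * sd(x)` with the sample
#' (n - 1) standard deviation. Scaling r with the data makes ApEn invariant
#' under affine transforms of the signal.
#'
#' @param x numeric vector, `length(x) >= 2`, all finite.
#' @param r_factor positive multiplier on the standard deviation; default 0.2.
#' @return Nonnegative scalar tolerance (0 for a constant series).
#' @export
tolerance_from_series <- function(x, r_factor = 0.2) {
  x <- as.numeric(x)
  if (length(x) < 2L || !all(is.finite(x))) {
    kin_abort("kin_error_argument", "x must be a finite numeric vector with n >= 2")
  }
  if (!is.numeric(r_factor) || length(r_factor) != 1L || r_factor <= 0) {
    kin_abort("kin_error_argument", "r_factor must be a positive scalar")
  }
  r_factor * stats::sd(x)
}

#' Approximate entropy of a time series
#'
#' Delayed-embedding approximate entropy (ApEn). Embedding vectors at
#' dimension d are \eqn{x_d(i) = (u(i), u(i+\tau), \dots, u(i+(d-1)\tau))},
#' \eqn{i = 1, \dots, M_d} with \eqn{M_d = n - (d-1)\tau}. For each i,
#' \eqn{C_i^d} is the fraction of vectors j (self-match included) whose
#' Chebyshev distance to vector i is at most r, and
#' \eqn{\Phi^d = M_d^{-1} \sum_i \ln C_i^d}. ApEn is
#' \eqn{\Phi^m - \Phi^{m+1}}: near 0 for regular, repetitive signals, larger
#' for irregular ones. With self-matches included the value is nonnegative
#' and a constant series yields exactly 0.
#'
#' @param x numeric vector of samples, all finite.
#' @param m pattern length (embedding dimension), a positive integer;
#'   default 2.
#' @param r match tolerance (same units as `x`), `r >= 0`. Typically
#'   [tolerance_from_series()] with factor 0.2. `r = 0` is permitted (matches
#'   become exact equality) but flagged with a warning on non-constant input.
#' @param tau embedding delay in samples, a positive integer; default 1.
#'   Typically chosen with [estimate_tau()].
#' @return An object of class `apen_result`: list with `apen`, `m`, `r`,
#'   `tau`, `n` and `m_vectors` (the number of dimension-m embedding
#'   vectors, `n - (m - 1) * tau`).
#' @examples
#' x <- sin(seq(0, 20 * pi, length.out = 600))
#' compute_apen(x, m = 2, r = 0.2 * sd(x), tau = 1)
#' @export
compute_apen <- function(x, m = 2L, r, tau = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m)
  tau <- as.integer(tau)
  if (!all(is.finite(x))) {
    kin_abort("kin_error_argument", "x must contain only finite values")
  }
  if (is.na(m) || m < 1L) kin_abort("kin_error_argument", "m must be a positive integer")
  if (is.na(tau) || tau < 1L) kin_abort("kin_error_argument", "tau must be a positive integer")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0) {
    kin_abort("kin_error_argument", "r must be a nonnegative finite scalar")
  }
  if (n - m * tau < 10L) {
    kin_abort("kin_error_insufficient_embedding",
              sprintf(paste0("insufficient embedding: need n - m*tau >= 10 ",
                             "vectors at dimension m+1, have %d (n = %d, m = %d, tau = %d)"),
                      n - m * tau, n, m, tau))
  }
  if (r == 0 && stats::var(x) > 0) {
    warning("r = 0 on a non-constant series: matches reduce to exact equality",
            call. = FALSE)
  }
  core <- apen_core(x, m, r, tau)
  structure(
    list(apen = core$apen, m = m, r = r, tau = tau, n = n,
         m_vectors = n - (m - 1L) * tau),
    class = "apen_result"
  )
}

#' @export
print.apen_result <- function(x, ...) {
  cat(sprintf("<apen_result> ApEn = %.6f  (m = %d, r = %.4g, tau = %d, n = %d)\n",
              x$apen, x$m, x$r, x$tau, x$n))
  invisible(x)
}

#' Reference (naive) approximate entropy
#'
#' A direct transcription of the ApEn definition in plain R: builds the
#' embedding matrix explicitly and counts Chebyshev matches row by row, one
#' O(M) comparison sweep per embedding vector, independently of the compiled
#' kernel used by [compute_apen()]. Intended as a cross-check at small n, not
#' for production use.
#'
#' @inheritParams compute_apen
#' @return The ApEn value as a bare numeric scalar.
#' @export
apen_reference <- function(x, m = 2L, r, tau = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  phi <- function(d) {
    M <- n - (d - 1L) * tau
    emb <- sapply(seq_len(d), function(k) x[(0:(M - 1L)) + (k - 1L) * tau + 1L])
    emb <- matrix(emb, nrow = M)
    logC <- numeric(M)
    for (i in seq_len(M)) {
      dist_i <- apply(abs(emb - matrix(emb[i, ], nrow = M, ncol = d, byrow = TRUE)),
                      1L, max)
      logC[i] <- log(sum(dist_i <= r) / M)
    }
    mean(logC)
  }
  if (n - m * tau < 1L) {
    kin_abort("kin_error_insufficient_embedding", "series too short for (m, tau)")
  }
  phi(m) - phi(m + 1L)
}
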