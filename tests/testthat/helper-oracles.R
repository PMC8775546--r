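# Independent closed-form / brute-force oracles used to cross-check the
# package's statistics. These deliberately re-derive each quantity from its
# textbook definition rather than calling the implementation path.

# Shared-denominator sample autocorrelation, direct from the definition.
acf_oracle <- function(x, k) {
  n <- length(x)
  xc <- x - mean(x)
  sum(xc[1:(n - k)] * xc[(1 + k):n]) / sum(xc^2)
}

# Welch two-sample t with Welch-Satterthwaite df, two-sided.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pooled-variance two-sample t (for the F = t^2 identity).
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# One-way fixed-effects ANOVA from explicit sums of squares.
anova_oracle <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  k <- length(groups); N <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, df1 = k - 1, df2 = N - k, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Brown-Forsythe Levene: one-way ANOVA on absolute deviations from the
# group medians.
levene_bf_oracle <- function(a, b) {
  za <- abs(a - median(a)); zb <- abs(b - median(b))
  anova_oracle(list(za, zb))
}

# Mann-Whitney / Wilcoxon rank-sum. W is the rank-sum statistic of the
# first sample minus its minimum. Exact p by enumeration of all
# choose(n1 + n2, n1) assignments; normal approximation with tie and
# continuity corrections otherwise.
mw_exact_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(n1 + n2, n1)
  Ws <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(Ws <= W), mean(Ws >= W))
  list(W = W, p = min(p, 1))
}

mw_normal_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nties <- table(pooled)
  z <- W - n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) - sum(nties^3 - nties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
  corr <- sign(z) * 0.5
  p <- 2 * min(pnorm((z - corr) / sigma, lower.tail = FALSE),
               pnorm((z - corr) / sigma))
  list(W = W, p = min(p, 1))
}

# Build a synthetic in-memory cohort and pull one side contrast out of the
# full pipeline; shared by the Monte-Carlo calibration checks.
knee_contrast_p <- function(seed, n_pd, n_oa, gamma, group) {
  spec <- cohort_spec(n_pd = n_pd, n_oa = n_oa, dances = "tango",
                      recordings_per_dance = 2L,
                      duration_range_min = c(0.5, 0.5),
                      channels = "knee_flexion", asymmetry_gamma = gamma,
                      seed = seed)
  sim <- simulate_cohort(spec)
  cfg <- pipeline_config(apen = apen_config(), channels = "knee_flexion")
  rep <- run_pipeline(sim$cohort, cfg)
  lab <- sprintf("%s knee_flexion ApEn left vs right", group)
  cr <- rep$contrasts[[lab]]
  agg <- rep$aggregates
  list(p = if (is.null(cr)) NA_real_ else cr$p_value,
       mean_left = mean(agg$mean_apen[agg$side == "left"]),
       mean_right = mean(agg$mean_apen[agg$side == "right"]))
}
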