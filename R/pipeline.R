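#' Configuration for the cohort analysis pipeline
#'
#' @param alpha significance level for contrasts; default 0.05.
#' @param alpha_normality Shapiro-Wilk level below which a contrast switches
#'   to the Mann-Whitney test; default 0.05.
#' @param apen an [apen_config()] used for every series.
#' @param channels channel allow-list as `<joint>_<measure>` names; defaults
#'   to the lower-limb set ([lower_limb_channels()]). Elbow channels are read
#'   but not analysed unless added here.
#' @param holm apply a Holm adjustment across the side contrasts (reported as
#'   an extra column; the per-contrast p values are always unadjusted).
#'   Default `FALSE`.
#' @param paired run the side contrasts as paired tests; default `FALSE`
#'   (the analysis unit is the participant-by-dance mean, compared unpaired).
#' @param unit `"participant_dance"` (default): one aggregate per participant
#'   and dance enters each contrast; `"participant"`: dances are pooled to
#'   one mean per participant.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, alpha_normality = 0.05,
                            apen = apen_config(),
                            channels = lower_limb_channels(),
                            holm = FALSE, paired = FALSE,
                            unit = c("participant_dance", "participant")) {
  unit <- match.arg(unit)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1 ||
      !is.numeric(alpha_normality) || alpha_normality <= 0 || alpha_normality >= 1) {
    kin_abort("kin_error_argument", "alpha levels must be in (0, 1)")
  }
  if (!inherits(apen, "apen_config")) {
    kin_abort("kin_error_argument", "apen must be an apen_config")
  }
  structure(
    list(alpha = alpha, alpha_normality = alpha_normality, apen = apen,
         channels = channels, holm = holm, paired = paired, unit = unit),
    class = "pipeline_config"
  )
}

# ---------------------------------------------------------------------------
# Assumption checking

#' Check distributional assumptions for a two-sample side contrast
#'
#' Runs Shapiro-Wilk normality per side, the Brown-Forsythe form of Levene's
#' variance-homogeneity test (median centring), and Tukey-fence outlier
#' flagging within each side (type-7 linear-interpolation quantiles; outlier
#' beyond 1.5 IQR from the quartiles, extreme beyond 3 IQR). Outliers are
#' reported, never removed. The decision is `"nonparametric"` iff either
#' side's Shapiro p-value falls below `alpha_normality`.
#'
#' @param left,right numeric vectors, each with at least 3 values.
#' @param alpha_normality Shapiro-Wilk level; default 0.05.
#' @return An object of class `assumption_report`: per-side Shapiro W and p,
#'   Levene statistic and p, an `outliers` data frame
#'   (`side`, `value`, `severity`), and `decision`.
#' @export
check_assumptions <- function(left, right, alpha_normality = 0.05) {
  left <- as.numeric(left); right <- as.numeric(right)
  if (length(left) < 3L || length(right) < 3L) {
    kin_abort("kin_error_insufficient_sample",
              sprintf("need n >= 3 per side for assumption checks (have %d, %d)",
                      length(left), length(right)))
  }
  sw <- function(v) {
    res <- tryCatch(stats::shapiro.test(v), error = function(e) NULL)
    if (is.null(res)) c(W = NA_real_, p = NA_real_)
    else c(W = unname(res$statistic), p = res$p.value)
  }
  sw_l <- sw(left); sw_r <- sw(right)
  y <- c(left, right)
  g <- factor(rep(c("left", "right"), c(length(left), length(right))))
  lev <- tryCatch({
    lt <- car::leveneTest(y ~ g, center = stats::median)
    c(stat = lt[["F value"]][1], p = lt[["Pr(>F)"]][1])
  }, error = function(e) c(stat = NA_real_, p = NA_real_))
  fences <- function(v, side) {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    sev <- ifelse(v < q[1] - 3 * iqr | v > q[2] + 3 * iqr, "extreme",
                  ifelse(v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr,
                         "outlier", NA_character_))
    keep <- !is.na(sev)
    data.frame(side = rep(side, sum(keep)), value = v[keep],
               severity = sev[keep], stringsAsFactors = FALSE)
  }
  outliers <- rbind(fences(left, "left"), fences(right, "right"))
  shapiro_p <- c(left = unname(sw_l["p"]), right = unname(sw_r["p"]))
  nonpar <- any(!is.na(shapiro_p) & shapiro_p < alpha_normality)
  structure(
    list(shapiro = data.frame(side = c("left", "right"),
                              W = c(sw_l["W"], sw_r["W"]),
                              p = unname(shapiro_p), row.names = NULL),
         levene_statistic = unname(lev["stat"]),
         levene_p = unname(lev["p"]),
         outliers = outliers,
         alpha_normality = alpha_normality,
         decision = if (nonpar) "nonparametric" else "parametric"),
    class = "assumption_report"
  )
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("<assumption_report> decision: %s\n", x$decision))
  cat(sprintf("  Shapiro-Wilk: left W = %.3f p = %.3g; right W = %.3f p = %.3g\n",
              x$shapiro$W[1], x$shapiro$p[1], x$shapiro$W[2], x$shapiro$p[2]))
  cat(sprintf("  Levene (Brown-Forsythe): F = %.3f, p = %.3g\n",
              x$levene_statistic, x$levene_p))
  cat(sprintf("  outliers flagged (kept in): %d (%d extreme)\n",
              nrow(x$outliers), sum(x$outliers$severity == "extreme")))
  invisible(x)
}

comparison_result <- function(label, test, statistic, df, p_value, effect,
                              summaries, assumptions = NULL,
                              flags = character(0)) {
  structure(
    list(label = label, test = test, statistic = statistic, df = df,
         p_value = p_value, effect = effect, summaries = summaries,
         assumptions = assumptions, flags = flags),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else
    sprintf("(%s)", paste(format(round(x$df, 2)), collapse = ", "))
  cat(sprintf("<comparison_result> %s\n  %s%s = %.4g, p = %.4g",
              x$label, switch(x$test, welch_t = "t", mann_whitney = "W",
                              anova_oneway = "F", x$test),
              dfs, x$statistic, x$p_value))
  if (!is.null(x$effect) && !is.na(x$effect)) {
    cat(sprintf(", effect = %.4g", x$effect))
  }
  cat("\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

two_sample_summaries <- function(a, b, names = c("left", "right")) {
  data.frame(group = names, n = c(length(a), length(b)),
             mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
             stringsAsFactors = FALSE)
}

#' Left-versus-right contrast with assumption-guided test choice
#'
#' Two-sided contrast of the left and right samples. When the assumption
#' report's decision is parametric, an unpaired Welch t-test
#' (Welch-Satterthwaite fractional df) is used — the behaviour of a default
#' two-sample `t.test`. When either side fails Shapiro-Wilk normality the
#' contrast falls back to the two-sided Mann-Whitney test (exact when both
#' samples are small and tie-free, normal approximation with tie and
#' continuity corrections otherwise). The effect direction is reported as
#' `mean(right) - mean(left)`. Two identical constant samples yield
#' statistic 0, p = 1, flagged `"degenerate"`.
#'
#' @param left,right numeric vectors.
#' @param assumptions an [`assumption_report`][check_assumptions]; computed
#'   from the data when `NULL`.
#' @param alpha_normality passed to [check_assumptions()] when needed.
#' @param label contrast label carried into reports.
#' @param paired run a paired test (sides must then be matched and equal
#'   length); default `FALSE`.
#' @return A `comparison_result`.
#' @export
compare_sides <- function(left, right, assumptions = NULL,
                          alpha_normality = 0.05, label = "left vs right",
                          paired = FALSE) {
  left <- as.numeric(left); right <- as.numeric(right)
  if (stats::var(c(left, right)) == 0) {
    return(comparison_result(
      label, "welch_t", statistic = 0, df = NA_real_, p_value = 1,
      effect = 0, summaries = two_sample_summaries(left, right),
      assumptions = assumptions, flags = "degenerate"
    ))
  }
  if (is.null(assumptions)) {
    assumptions <- check_assumptions(left, right, alpha_normality)
  }
  if (assumptions$decision == "parametric") {
    tt <- stats::t.test(left, right, paired = paired)
    res <- comparison_result(
      label, "welch_t", statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value,
      effect = mean(right) - mean(left),
      summaries = two_sample_summaries(left, right),
      assumptions = assumptions
    )
  } else {
    wt <- suppressWarnings(stats::wilcox.test(left, right, paired = paired))
    res <- comparison_result(
      label, "mann_whitney", statistic = unname(wt$statistic),
      df = NA_real_, p_value = wt$p.value,
      effect = mean(right) - mean(left),
      summaries = two_sample_summaries(left, right),
      assumptions = assumptions
    )
  }
  res
}

#' Welch comparison of two groups
#'
#' Unpaired two-sided Welch t-test (the default two-sample `t.test`), used
#' for between-group comparisons of demographics and recording-level
#' quantities (session length, embedding delay, autocorrelation at the
#' delay). Identical constant groups yield statistic 0, p = 1, flagged.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param label contrast label.
#' @param names group display names.
#' @return A `comparison_result` with `test = "welch_t"`.
#' @export
compare_groups <- function(a, b, label = "group comparison",
                           names = c("A", "B")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    kin_abort("kin_error_insufficient_sample",
              "need n >= 2 per group for a Welch comparison")
  }
  if (stats::var(c(a, b)) == 0) {
    return(comparison_result(
      label, "welch_t", statistic = 0, df = NA_real_, p_value = 1,
      effect = 0, summaries = two_sample_summaries(a, b, names),
      flags = "degenerate"
    ))
  }
  tt <- stats::t.test(a, b)
  comparison_result(
    label, "welch_t", statistic = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value,
    effect = mean(b) - mean(a),
    summaries = two_sample_summaries(a, b, names)
  )
}

#' One-way fixed-effects ANOVA across dance types
#'
#' Classic one-way ANOVA F statistic with (k - 1, N - k) degrees of freedom
#' under equal-variance pooling.
#'
#' @param values_by_dance named list of numeric vectors, one per dance,
#'   each with at least 2 values; at least 2 dances.
#' @param label contrast label.
#' @return A `comparison_result` with `test = "anova_oneway"` and
#'   `df = c(k - 1, N - k)`.
#' @export
compare_across_dances <- function(values_by_dance, label = "across dances") {
  if (!is.list(values_by_dance) || length(values_by_dance) < 2L) {
    kin_abort("kin_error_argument", "need at least 2 dance groups")
  }
  ns <- vapply(values_by_dance, length, integer(1))
  if (any(ns < 2L)) {
    kin_abort("kin_error_insufficient_sample",
              sprintf("dance group(s) with n < 2: %s",
                      paste(names(values_by_dance)[ns < 2L], collapse = ", ")))
  }
  y <- unlist(values_by_dance, use.names = FALSE)
  g <- factor(rep(names(values_by_dance), ns))
  k <- nlevels(g); N <- length(y)
  summaries <- data.frame(group = names(values_by_dance), n = as.integer(ns),
                          mean = vapply(values_by_dance, mean, numeric(1)),
                          sd = vapply(values_by_dance, stats::sd, numeric(1)),
                          row.names = NULL, stringsAsFactors = FALSE)
  if (stats::var(y) == 0) {
    return(comparison_result(label, "anova_oneway", statistic = 0,
                             df = c(k - 1, N - k), p_value = 1,
                             effect = NA_real_, summaries = summaries,
                             flags = "degenerate"))
  }
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  comparison_result(
    label, "anova_oneway", statistic = unname(ow$statistic),
    df = unname(ow$parameter), p_value = ow$p.value, effect = NA_real_,
    summaries = summaries
  )
}

# ---------------------------------------------------------------------------
# Per-series analysis and aggregation

#' Analyse every allowed channel of every recording in a cohort
#'
#' Runs [analyze_series()] per (recording, channel) and tabulates results
#' including per-recording failures (constant series, delay not found,
#' series too short), which are recorded with a status tag and excluded from
#' downstream aggregation — never silently dropped.
#'
#' @param cohort a [`cohort`][cohort].
#' @param config a [pipeline_config()].
#' @return Data frame with one row per recording x analysed channel:
#'   identifiers, `n`, `duration_min`, `tau`, `acf_at_tau`, `r`, `apen`,
#'   `mean_angle`, `status` (`"ok"` or a failure tag).
#' @export
analyze_cohort <- function(cohort, config = pipeline_config()) {
  rows <- list()
  for (rec in cohort$recordings) {
    for (ch in rec$channels) {
      jm <- paste(ch$joint, ch$measure, sep = "_")
      if (!jm %in% config$channels) next
      res <- tryCatch(analyze_series(ch$values, config$apen),
                      kinentropy_error = function(e) e)
      if (inherits(res, "kinentropy_error")) {
        status <- setdiff(class(res),
                          c("kinentropy_error", "error", "condition"))[1]
        status <- sub("^kin_error_", "", status)
        rows[[length(rows) + 1L]] <- data.frame(
          recording_id = rec$recording_id, participant_id = rec$participant_id,
          group = rec$group, dance = rec$dance, joint = ch$joint,
          measure = ch$measure, side = ch$side, n = ch$n,
          duration_min = rec$duration_min, tau = NA_integer_,
          acf_at_tau = NA_real_, r = NA_real_, apen = NA_real_,
          mean_angle = NA_real_, status = status, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          recording_id = rec$recording_id, participant_id = rec$participant_id,
          group = rec$group, dance = rec$dance, joint = ch$joint,
          measure = ch$measure, side = ch$side, n = ch$n,
          duration_min = rec$duration_min, tau = res$tau$tau,
          acf_at_tau = res$tau$acf_at_tau, r = res$r, apen = res$apen$apen,
          mean_angle = res$mean_angle, status = "ok", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    kin_abort("kin_error_fatal", "no channels matched the allow-list")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-series results by participant, dance, joint measure and side
#'
#' Arithmetic mean of entropy and of mean angle over each participant's
#' recordings of a given dance, per channel and side — the analysis unit for
#' the side contrasts. Only rows with `status == "ok"` contribute.
#'
#' @param per_series output of [analyze_cohort()].
#' @return Data frame with one row per unique (participant, group, dance,
#'   joint, measure, side): `mean_apen`, `mean_angle`, `n_recordings`.
#' @export
aggregate_results <- function(per_series) {
  ok <- per_series[per_series$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) {
    kin_abort("kin_error_fatal", "no successfully analysed series to aggregate")
  }
  keys <- c("participant_id", "group", "dance", "joint", "measure", "side")
  means <- stats::aggregate(ok[, c("apen", "mean_angle")], by = ok[, keys],
                            FUN = mean)
  counts <- stats::aggregate(list(n_recordings = ok$apen), by = ok[, keys],
                             FUN = length)
  agg <- merge(means, counts, by = keys, sort = FALSE)
  names(agg)[names(agg) == "apen"] <- "mean_apen"
  agg <- agg[do.call(order, agg[, keys]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# ---------------------------------------------------------------------------
# Full pipeline

side_contrast_data <- function(agg, grp, jm, metric, unit) {
  joint <- sub("_.*$", "", jm)
  measure <- sub("^.*_", "", jm)
  sub <- agg[agg$group == grp & agg$joint == joint & agg$measure == measure, ,
             drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  if (unit == "participant") {
    sub <- stats::aggregate(sub[, c("mean_apen", "mean_angle")],
                            by = sub[, c("participant_id", "side")], FUN = mean)
    key <- "participant_id"
  } else {
    key <- c("participant_id", "dance")
  }
  l <- sub[sub$side == "left", , drop = FALSE]
  r <- sub[sub$side == "right", , drop = FALSE]
  lk <- do.call(paste, c(l[, key, drop = FALSE], sep = "\r"))
  rk <- do.call(paste, c(r[, key, drop = FALSE], sep = "\r"))
  common <- intersect(lk, rk)
  dropped <- length(union(lk, rk)) - length(common)
  ord <- order(common)
  list(left = l[[metric]][match(common, lk)][ord],
       right = r[[metric]][match(common, rk)][ord],
       n_dropped_one_sided = dropped)
}

#' Run the full cohort analysis
#'
#' Loads (or accepts) a cohort, analyses every allowed channel of every
#' recording, aggregates by participant, dance, joint measure and side, and
#' runs the statistical battery: per group and joint measure a left-vs-right
#' contrast of mean entropy and of mean angle (assumption-checked, Welch or
#' Mann-Whitney); between-group Welch comparisons of recording length,
#' embedding delay and autocorrelation at the delay; and across-dance
#' one-way ANOVAs of recording length and delay. Contrasts with insufficient
#' data are reported as skipped, never fabricated. The run is fully
#' deterministic given the input files.
#'
#' @param x manifest path, a [`cohort`][cohort], or a list of
#'   [`recording`][recording] objects.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes `results.csv`
#'   (aggregates), `contrasts.csv`, `qc.csv` and `summary.json`.
#' @return An object of class `analysis_report`: list with `per_series`,
#'   `aggregates`, `contrasts` (list of `comparison_result`),
#'   `group_comparisons`, `anovas`, `skipped` (data frame), `exclusions`,
#'   `config`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir = NULL) {
  coh <- if (is.character(x)) load_cohort(x)
         else if (inherits(x, "cohort")) x
         else if (is.list(x)) cohort(x)
         else kin_abort("kin_error_argument", "x must be a manifest path, cohort or recording list")

  per_series <- analyze_cohort(coh, config)
  agg <- aggregate_results(per_series)
  ok <- per_series[per_series$status == "ok", , drop = FALSE]

  skipped <- data.frame(label = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  skip <- function(label, reason) {
    skipped <<- rbind(skipped, data.frame(label = label, reason = reason,
                                          stringsAsFactors = FALSE))
  }

  contrasts <- list()
  groups_present <- sort(unique(agg$group))
  for (grp in groups_present) {
    for (jm in config$channels) {
      for (metric in c("mean_apen", "mean_angle")) {
        what <- if (metric == "mean_apen") "ApEn" else "mean angle"
        label <- sprintf("%s %s %s left vs right", grp, jm, what)
        d <- side_contrast_data(agg, grp, jm, metric, config$unit)
        if (is.null(d) || length(d$left) < 3L) {
          skip(label, "fewer than 3 matched participant-dance units per side")
          next
        }
        cr <- tryCatch(
          compare_sides(d$left, d$right,
                        alpha_normality = config$alpha_normality,
                        label = label, paired = config$paired),
          kinentropy_error = function(e) e)
        if (inherits(cr, "kinentropy_error")) {
          skip(label, conditionMessage(cr))
        } else {
          if (d$n_dropped_one_sided > 0) {
            cr$flags <- c(cr$flags,
                          sprintf("%d one-sided unit(s) excluded",
                                  d$n_dropped_one_sided))
          }
          contrasts[[label]] <- cr
        }
      }
    }
  }
  if (config$holm && length(contrasts)) {
    padj <- stats::p.adjust(vapply(contrasts, function(cr) cr$p_value,
                                   numeric(1)), method = "holm")
    for (i in seq_along(contrasts)) contrasts[[i]]$p_holm <- unname(padj[i])
  }

  # Between-group comparisons of recording-level quantities
  group_comparisons <- list()
  if (all(c("PD", "OA") %in% ok$group)) {
    per_rec <- unique(ok[, c("recording_id", "group", "duration_min")])
    vars <- list(
      "recording length (min)" = list(
        a = per_rec$duration_min[per_rec$group == "PD"],
        b = per_rec$duration_min[per_rec$group == "OA"]),
      "tau (samples)" = list(a = ok$tau[ok$group == "PD"],
                             b = ok$tau[ok$group == "OA"]),
      "acf at tau" = list(a = ok$acf_at_tau[ok$group == "PD"],
                          b = ok$acf_at_tau[ok$group == "OA"])
    )
    for (nm in names(vars)) {
      v <- vars[[nm]]
      label <- sprintf("PD vs OA %s", nm)
      cr <- tryCatch(compare_groups(v$a, v$b, label = label,
                                    names = c("PD", "OA")),
                     kinentropy_error = function(e) e)
      if (inherits(cr, "kinentropy_error")) skip(label, conditionMessage(cr))
      else group_comparisons[[label]] <- cr
    }
  } else {
    skip("PD vs OA comparisons", "both groups not present")
  }

  # Across-dance ANOVAs
  anovas <- list()
  per_rec <- unique(ok[, c("recording_id", "dance", "duration_min")])
  dance_vars <- list(
    "recording length (min) across dances" =
      split(per_rec$duration_min, per_rec$dance),
    "tau (samples) across dances" = split(ok$tau, ok$dance)
  )
  for (nm in names(dance_vars)) {
    vb <- Filter(function(v) length(v) >= 2L, dance_vars[[nm]])
    if (length(vb) < 2L) {
      skip(nm, "fewer than 2 dances with n >= 2")
      next
    }
    cr <- tryCatch(compare_across_dances(vb, label = nm),
                   kinentropy_error = function(e) e)
    if (inherits(cr, "kinentropy_error")) skip(nm, conditionMessage(cr))
    else anovas[[nm]] <- cr
  }

  report <- structure(
    list(per_series = per_series, aggregates = agg, contrasts = contrasts,
         group_comparisons = group_comparisons, anovas = anovas,
         skipped = skipped, exclusions = coh$exclusions, config = config),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  n_ok <- sum(x$per_series$status == "ok")
  cat(sprintf("<analysis_report> %d series analysed (%d failed QC), %d aggregates\n",
              n_ok, nrow(x$per_series) - n_ok, nrow(x$aggregates)))
  for (cr in x$contrasts) {
    star <- if (cr$p_value < x$config$alpha) " *" else ""
    cat(sprintf("  %-45s %s = %8.3f  p = %.4f%s\n", cr$label,
                switch(cr$test, welch_t = "t", mann_whitney = "W", "F"),
                cr$statistic, cr$p_value, star))
  }
  if (nrow(x$skipped)) {
    cat(sprintf("  (%d contrast(s) skipped)\n", nrow(x$skipped)))
  }
  invisible(x)
}

flatten_comparisons <- function(crs) {
  if (length(crs) == 0L) {
    return(data.frame(label = character(0), test = character(0),
                      statistic = numeric(0), df1 = numeric(0),
                      df2 = numeric(0), p_value = numeric(0),
                      effect = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(crs, function(cr) {
    s <- cr$summaries
    two <- nrow(s) == 2L
    a <- cr$assumptions
    data.frame(
      label = cr$label, test = cr$test, statistic = cr$statistic,
      df1 = if (length(cr$df) >= 1L) cr$df[1] else NA_real_,
      df2 = if (length(cr$df) >= 2L) cr$df[2] else NA_real_,
      p_value = cr$p_value,
      p_holm = if (!is.null(cr$p_holm)) cr$p_holm else NA_real_,
      effect = if (is.null(cr$effect)) NA_real_ else cr$effect,
      n_1 = if (two) s$n[1] else NA_real_,
      n_2 = if (two) s$n[2] else NA_real_,
      mean_1 = if (two) s$mean[1] else NA_real_,
      mean_2 = if (two) s$mean[2] else NA_real_,
      sd_1 = if (two) s$sd[1] else NA_real_,
      sd_2 = if (two) s$sd[2] else NA_real_,
      shapiro_p_left = if (!is.null(a)) a$shapiro$p[1] else NA_real_,
      shapiro_p_right = if (!is.null(a)) a$shapiro$p[2] else NA_real_,
      levene_p = if (!is.null(a)) a$levene_p else NA_real_,
      n_outliers = if (!is.null(a)) nrow(a$outliers) else NA_integer_,
      n_extreme = if (!is.null(a)) sum(a$outliers$severity == "extreme")
                  else NA_integer_,
      decision = if (!is.null(a)) a$decision else NA_character_,
      flags = paste(cr$flags, collapse = "; "),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

write_csv_det <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  esc <- function(v) {
    v <- as.character(v)
    v[is.na(v)] <- "NA"
    needs <- grepl("[\",\n]", v)
    v[needs] <- paste0("\"", gsub("\"", "\"\"", v[needs]), "\"")
    v
  }
  fmt <- function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.15g", col)
      out[is.na(col)] <- "NA"
      out
    } else esc(col)
  }
  body <- do.call(cbind, lapply(df, fmt))
  writeLines(c(paste(names(df), collapse = ","),
               if (nrow(df)) apply(matrix(body, nrow = nrow(df)), 1L,
                                   paste, collapse = ",")),
             con, sep = "\n")
  invisible(path)
}

#' Write an analysis report's tables and machine-readable summary
#'
#' Emits `results.csv` (one row per aggregate record), `contrasts.csv` (one
#' row per statistical contrast, including group comparisons and ANOVAs),
#' `qc.csv` (one row per recording x channel with status, delay, tolerance),
#' and `summary.json`. All writers are deterministic: the same report
#' produces byte-identical files.
#'
#' @param report an [`analysis_report`][run_pipeline].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_contrasts <- flatten_comparisons(c(report$contrasts,
                                         report$group_comparisons,
                                         report$anovas))
  write_csv_det(report$aggregates, file.path(out_dir, "results.csv"))
  write_csv_det(all_contrasts, file.path(out_dir, "contrasts.csv"))
  write_csv_det(report$per_series, file.path(out_dir, "qc.csv"))
  summary <- list(
    n_recordings = length(unique(report$per_series$recording_id)),
    n_series = nrow(report$per_series),
    n_series_ok = sum(report$per_series$status == "ok"),
    n_excluded_files = nrow(report$exclusions),
    groups = as.list(table(report$aggregates$group[!duplicated(
      report$aggregates$participant_id)])),
    config = list(
      alpha = report$config$alpha,
      alpha_normality = report$config$alpha_normality,
      m = report$config$apen$m, r_factor = report$config$apen$r_factor,
      acf_threshold = report$config$apen$acf_threshold,
      max_shift_fraction = report$config$apen$max_shift_fraction,
      tau_mode = report$config$apen$tau_mode,
      channels = report$config$channels, unit = report$config$unit,
      paired = report$config$paired, holm = report$config$holm),
    aggregates = report$aggregates,
    contrasts = all_contrasts,
    skipped = report$skipped
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
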