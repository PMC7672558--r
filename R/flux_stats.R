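#' Reciprocal-logit transform for percentage data
#'
#' Percentage metrics (components expressed as a percentage of a parent
#' flux) are transformed before testing as `Y -> 1/Y` followed by
#' `Y -> logit(Y)`, i.e. `ln((1/y) / (1 - 1/y)) = -ln(y - 1)`. The
#' composite is strictly decreasing in `y` and is defined only for
#' `y > 1`: on the percent scale `1/y` must fall inside (0, 1), so
#' values at or below 1 percent are a domain error rather than being
#' silently clamped.
#'
#' @param y numeric vector of percentages, all `> 1`.
#' @return Transformed values.
#' @export
reciprocal_logit <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("y must be finite numeric")
  if (any(y <= 1))
    stop("reciprocal-logit is defined for percent values > 1 only ",
         "(1/y must lie strictly inside (0,1)); got y = ",
         paste(signif(y[y <= 1], 4), collapse = ", "))
  r <- 1 / y
  log(r / (1 - r))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis z-statistics
#' into `K2 = Z_skew^2 + Z_kurt^2`, referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires `n >= 8` for the
#' skewness approximation to hold.
#'
#' @param x numeric sample, `n >= 8`, non-constant.
#' @return List with `statistic` (K2), `p`, and `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  if (sd(x) == 0) stop("sample is constant")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness z (D'Agostino 1970, via the Johnson SU approximation)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xx * sqrt(2 / (a - 4))
  term <- (1 - 2 / a) / denom
  z_kurt <- ((1 - 2 / (9 * a)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       n = n)
}

gate_one_test <- function(x, test) {
  run <- switch(test,
    shapiro_wilk = function(v) {
      if (length(v) < 3) stop("needs n >= 3")
      stats::shapiro.test(v)$p.value
    },
    kolmogorov_smirnov = function(v) {
      if (length(v) < 5) stop("needs n >= 5")
      nortest::lillie.test(v)$p.value
    },
    dagostino_pearson = function(v) dagostino_pearson(v)$p)
  res <- tryCatch(list(p = run(x), applicable = TRUE, reason = ""),
                  error = function(e) list(p = NA_real_, applicable = FALSE,
                                           reason = conditionMessage(e)))
  res
}

#' Three-test normality gate for two-group comparisons
#'
#' Runs the Kolmogorov-Smirnov (Lilliefors-corrected), D'Agostino-Pearson
#' and Shapiro-Wilk normality tests on both samples. The comparison is
#' treated as parametric only when every *applicable* test passes
#' (`p > alpha`) in both groups (`rule = "all"`, the conservative
#' default) or when a majority do (`rule = "majority"`). Tests whose
#' sample-size or variance requirements are not met (e.g.
#' D'Agostino-Pearson at `n < 8`, any test on a constant sample) are
#' recorded as not-applicable and do not fail the gate; if no test is
#' applicable at all the gate falls back to the non-parametric branch.
#'
#' @param sample_a,sample_b numeric vectors, each with at least 3
#'   observations.
#' @param alpha gate significance level (default 0.05).
#' @param rule `"all"` or `"majority"`, see above.
#' @return List with `decision` (`"parametric"`/`"nonparametric"`) and
#'   `report`, a data frame of per-test p-values and applicability.
#' @export
normality_gate <- function(sample_a, sample_b, alpha = 0.05,
                           rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop("normality gate requires at least 3 observations per group")
  tests <- c("kolmogorov_smirnov", "dagostino_pearson", "shapiro_wilk")
  rows <- list()
  for (g in c("a", "b")) {
    x <- if (g == "a") sample_a else sample_b
    for (tst in tests) {
      r <- gate_one_test(x, tst)
      rows[[length(rows) + 1]] <-
        data.frame(group = g, test = tst, p = r$p, applicable = r$applicable,
                   reason = r$reason, stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  appl <- report[report$applicable, , drop = FALSE]
  decision <- if (nrow(appl) == 0) {
    "nonparametric"
  } else if (rule == "all") {
    if (all(appl$p > alpha)) "parametric" else "nonparametric"
  } else {
    if (mean(appl$p > alpha) > 0.5) "parametric" else "nonparametric"
  }
  list(decision = decision, report = report)
}

#' Percent change of hypoxia relative to normoxia
#'
#' `100 * (mean(hypoxia) - mean(normoxia)) / mean(normoxia)`. Reductions
#' come out negative (an "80% reduction" is -80).
#'
#' @param normoxia,hypoxia numeric vectors of the metric per group.
#' @return Percent change (scalar).
#' @export
percent_change <- function(normoxia, hypoxia) {
  mn <- mean(normoxia)
  if (mn == 0) stop("normoxia mean is zero; percent change undefined")
  100 * (mean(hypoxia) - mn) / mn
}

#' Delta-method standard error of the percent change
#'
#' Treats the two group means as independent estimates and propagates
#' their standard errors through the ratio.
#'
#' @inheritParams percent_change
#' @return Approximate standard error of [percent_change()].
#' @export
percent_change_se <- function(normoxia, hypoxia) {
  mn <- mean(normoxia); mh <- mean(hypoxia)
  if (mn == 0) stop("normoxia mean is zero")
  se_n2 <- var(normoxia) / length(normoxia)
  se_h2 <- var(hypoxia) / length(hypoxia)
  100 * sqrt(se_h2 / mn^2 + mh^2 * se_n2 / mn^4)
}

#' Normality-gated two-group comparison
#'
#' The full testing procedure for one derived metric: optionally apply
#' the reciprocal-logit transform (mandatory for percentage metrics),
#' run the three-test normality gate on the (transformed) data, then
#' test hypoxia against normoxia with the selected test: Welch's
#' unpaired t-test or Mann-Whitney when `design = "unpaired"`, paired
#' t-test or Wilcoxon signed-rank when `design = "paired"`. The percent
#' change is always computed on the raw (untransformed) scale.
#'
#' @param normoxia,hypoxia numeric metric values per condition.
#' @param design `"unpaired"` (default) or `"paired"`; paired requires
#'   equal group sizes with matching order.
#' @param transform apply [reciprocal_logit()] before the gate and test
#'   (set for percentage metrics).
#' @param alpha normality-gate level.
#' @param gate_rule see [normality_gate()].
#' @param force_test bypass the gate: `"t"` or `"wilcoxon"`.
#' @param metric optional metric name carried into the result.
#' @return A `group_comparison` list: group sizes and raw-scale
#'   summaries, transform and gate provenance, `test_used`, `statistic`,
#'   `p`, and `percent_change`.
#' @export
compare_groups <- function(normoxia, hypoxia,
                           design = c("unpaired", "paired"),
                           transform = FALSE, alpha = 0.05,
                           gate_rule = "all", force_test = NULL,
                           metric = NA_character_) {
  design <- match.arg(design)
  if (design == "paired" && length(normoxia) != length(hypoxia))
    stop("paired design requires equal group sizes")
  xn <- if (transform) reciprocal_logit(normoxia) else normoxia
  xh <- if (transform) reciprocal_logit(hypoxia) else hypoxia
  gate <- NULL
  if (is.null(force_test)) {
    gate <- normality_gate(xn, xh, alpha = alpha, rule = gate_rule)
    branch <- if (gate$decision == "parametric") "t" else "wilcoxon"
  } else {
    branch <- match.arg(force_test, c("t", "wilcoxon"))
  }
  paired <- design == "paired"
  if (branch == "t") {
    ht <- stats::t.test(xh, xn, paired = paired, var.equal = FALSE)
    test_used <- if (paired) "paired_t" else "unpaired_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(xh, xn, paired = paired))
    test_used <- if (paired) "wilcoxon_paired" else "mann_whitney"
  }
  structure(list(
    metric = metric, design = design,
    n = c(normoxia = length(normoxia), hypoxia = length(hypoxia)),
    mean = c(normoxia = mean(normoxia), hypoxia = mean(hypoxia)),
    sd = c(normoxia = sd(normoxia), hypoxia = sd(hypoxia)),
    transform = if (transform) "reciprocal_logit" else "none",
    normality = if (is.null(gate)) NULL else gate$report,
    gate_decision = if (is.null(gate)) sprintf("forced_%s", branch)
                    else gate$decision,
    test_used = test_used,
    statistic = unname(ht$statistic), p = unname(ht$p.value),
    percent_change = percent_change(normoxia, hypoxia)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  pc <- x$percent_change
  dirn <- if (pc < 0) sprintf("%.1f%% reduction", -pc)
          else sprintf("+%.1f%%", pc)
  cat(sprintf("%s: %s vs normoxia (%s, %s; p = %.4g)\n",
              if (is.na(x$metric)) "metric" else x$metric, dirn,
              x$test_used, x$transform, x$p))
  invisible(x)
}

#' Metrics tested on the percentage scale
#'
#' Percentage-of-parent metrics must be reciprocal-logit transformed
#' before testing; this registry is how [compare_profiles()] enforces
#' that.
#' @format Character vector of profile column names.
#' @export
PERCENT_METRICS <- c("CR_pct_MR", "PL_pct_MR", "SRC_pct_MR")

FLUX_METRICS <- c("MR", "CR", "PL", "SRC", "NG_ECAR", "GLYCO_ECAR",
                  "GLYCO_CAP", "GLYCO_RES", "CR_pct_MR", "PL_pct_MR",
                  "SRC_pct_MR", "ratio_PrG", "ratio_PsG", "ratio_FCCP")

#' Condition contrasts for every derived metric of a profile table
#'
#' Runs [compare_groups()] for each bioenergetic metric column of a
#' [group_profile_table()] result, applying the reciprocal-logit
#' transform to the registered percentage metrics. Wells with undefined
#' values for a metric are dropped from that metric's comparison.
#'
#' @param profiles a [group_profile_table()] data frame with rows of
#'   both conditions.
#' @param design,alpha,gate_rule passed to [compare_groups()].
#' @return Data frame, one row per metric: group sizes, raw means,
#'   transform, gate decision, test used, statistic, p, percent change.
#' @export
compare_profiles <- function(profiles, design = "unpaired", alpha = 0.05,
                             gate_rule = "all") {
  stopifnot(all(c("condition", FLUX_METRICS) %in% names(profiles)))
  rows <- lapply(FLUX_METRICS, function(m) {
    vals <- profiles[[m]]
    ok <- !is.na(vals)
    nvals <- vals[ok & profiles$condition == "normoxia"]
    hvals <- vals[ok & profiles$condition == "hypoxia"]
    cmp <- compare_groups(nvals, hvals, design = design,
                          transform = m %in% PERCENT_METRICS,
                          alpha = alpha, gate_rule = gate_rule, metric = m)
    data.frame(metric = m, n_normoxia = cmp$n[["normoxia"]],
               n_hypoxia = cmp$n[["hypoxia"]],
               mean_normoxia = cmp$mean[["normoxia"]],
               mean_hypoxia = cmp$mean[["hypoxia"]],
               transform = cmp$transform, gate = cmp$gate_decision,
               test_used = cmp$test_used, statistic = cmp$statistic,
               p = cmp$p, percent_change = cmp$percent_change,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
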