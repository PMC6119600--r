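#' Normalize values to a control group, per experiment
#'
#' Divides every value by the mean of the control group's values within
#' the same experiment, so the control maps to exactly 1.0. This is the
#' normalize-then-average design used for blot quantification and
#' per-experiment imaging summaries.
#'
#' @param values numeric vector.
#' @param group group label per value.
#' @param control the control group's label.
#' @param experiment optional experiment label per value; `NULL` treats
#'   all values as one experiment. Every experiment must contain the
#'   control with a nonzero mean, otherwise an error names the experiment.
#' @return Numeric vector of normalized values (same order as input).
#' @export
#' @examples
#' normalize_to_control(c(2, 3), c("vehicle", "treated"), "vehicle")
normalize_to_control <- function(values, group, control, experiment = NULL) {
  stopifnot(is.numeric(values), length(values) == length(group))
  if (is.null(experiment)) experiment <- rep("1", length(values))
  stopifnot(length(experiment) == length(values))
  out <- numeric(length(values))
  for (e in unique(experiment)) {
    sel <- experiment == e
    ctl <- values[sel & group == control]
    if (length(ctl) == 0)
      stop("control group '", control, "' missing in experiment '", e, "'")
    m <- mean(ctl)
    if (!is.finite(m) || m == 0)
      stop("control group '", control, "' has zero (or non-finite) mean in ",
           "experiment '", e, "'")
    out[sel] <- values[sel] / m
  }
  out
}

#' Group summary: mean, SEM, n
#'
#' SEM is the sample standard deviation (n-1 denominator) divided by
#' sqrt(n); for a single value it is reported as missing (NA), not zero.
#'
#' @param values numeric vector, n >= 1.
#' @param label group label recorded in the output.
#' @return One-row data.frame: `label`, `n`, `mean`, `sd`, `sem`.
#' @export
#' @examples
#' group_summary(c(1, 2, 3))  # sem = 1/sqrt(3)
group_summary <- function(values, label = NA_character_) {
  if (length(values) == 0) stop("group_summary() needs n >= 1 values")
  n <- length(values)
  s <- if (n > 1) sd(values) else NA_real_
  data.frame(label = label, n = n, mean = mean(values), sd = s,
             sem = if (n > 1) s / sqrt(n) else NA_real_)
}

.comparison_row <- function(test, comparison, statistic, df, p_raw,
                            family_size, alpha) {
  p_adj <- min(1, p_raw * family_size)
  data.frame(test = test, comparison = comparison, statistic = statistic,
             df = df, p_raw = p_raw, p_adjusted = p_adj,
             family_size = family_size, significant = p_adj < alpha)
}

#' Two-tailed two-sample t-test
#'
#' Classical Student's t-test (pooled variance, the default) or Welch's
#' variant, two-tailed. Degenerate input with zero variance in both
#' groups and equal means returns t = 0, p = 1 rather than an error.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param variance `"pooled"` (Student) or `"welch"`.
#' @param alpha significance level (default 0.05).
#' @param comparison label recorded in the output row.
#' @return One-row comparison data.frame: `test`, `comparison`,
#'   `statistic`, `df`, `p_raw`, `p_adjusted` (= `p_raw`, family of 1),
#'   `family_size`, `significant`.
#' @export
#' @examples
#' t_test_two_tailed(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
t_test_two_tailed <- function(a, b, variance = c("pooled", "welch"),
                              alpha = 0.05, comparison = "a vs b") {
  variance <- match.arg(variance)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(.comparison_row("t_two_tailed", comparison, 0,
                             length(a) + length(b) - 2, 1, 1L, alpha))
    stop("both groups are constant with different means: t is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = (variance == "pooled"),
                      alternative = "two.sided")
  .comparison_row("t_two_tailed", comparison,
                  unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, 1L, alpha)
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' Computes the one-way ANOVA F-test over all groups, followed by
#' pairwise two-tailed t-tests whose raw p-values are Bonferroni-adjusted
#' (`p_adjusted = min(1, p_raw * family_size)`). The comparison family is
#' a required choice with no silent default between analyses:
#' `"vs_reference"` compares every group against the reference (family
#' size g - 1, e.g. rings 2..4 against ring 1), `"all_pairs"` compares
#' all pairs (family size g(g-1)/2).
#'
#' @param values numeric vector.
#' @param group group label per value; >= 2 groups, each n >= 2.
#' @param family `"vs_reference"` or `"all_pairs"`.
#' @param reference reference group label (required for
#'   `"vs_reference"`).
#' @param variance passed to the pairwise [t_test_two_tailed()].
#' @param alpha significance level (default 0.05).
#' @return A list of class `anova_bonferroni`: `$anova` (one row with F,
#'   df1, df2, p) and `$pairwise` (one comparison row per pair with
#'   `family_size` populated).
#' @export
#' @examples
#' v <- c(0, 1, 2, 1, 2, 3, 2, 3, 4)
#' g <- rep(c("a", "b", "c"), each = 3)
#' anova_bonferroni(v, g, family = "all_pairs")$anova  # F = 3, p = 0.125
anova_bonferroni <- function(values, group,
                             family = c("vs_reference", "all_pairs"),
                             reference = NULL,
                             variance = c("pooled", "welch"),
                             alpha = 0.05) {
  family <- match.arg(family)
  variance <- match.arg(variance)
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  levs <- unique(group)
  if (length(levs) < 2) stop("anova_bonferroni() needs >= 2 groups")
  ns <- table(group)
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (family == "vs_reference") {
    if (is.null(reference)) stop("family = 'vs_reference' requires a reference")
    if (!reference %in% levs)
      stop("reference group '", reference, "' not present")
  }

  ## one-way ANOVA (fixed effects, equal-variance F)
  grand <- mean(values)
  ss_between <- sum(vapply(levs, function(l)
    sum(group == l) * (mean(values[group == l]) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(levs, function(l) {
    v <- values[group == l]; sum((v - mean(v))^2) }, numeric(1)))
  df1 <- length(levs) - 1
  df2 <- length(values) - length(levs)
  f <- if (ss_within == 0) {
    if (ss_between == 0) 0 else Inf
  } else (ss_between / df1) / (ss_within / df2)
  p_f <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  anova_row <- data.frame(test = "anova_oneway", statistic = f,
                          df1 = df1, df2 = df2, p_raw = p_f,
                          significant = p_f < alpha)

  g <- length(levs)
  if (family == "vs_reference") {
    pairs <- lapply(setdiff(levs, reference), function(l) c(reference, l))
    fam <- g - 1L
  } else {
    cmb <- utils::combn(levs, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
    fam <- as.integer(g * (g - 1) / 2)
  }
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    row <- t_test_two_tailed(values[group == pr[1]], values[group == pr[2]],
                             variance = variance, alpha = alpha,
                             comparison = paste(pr[1], "vs", pr[2]))
    row$family_size <- fam
    row$p_adjusted <- min(1, row$p_raw * fam)
    row$significant <- row$p_adjusted < alpha
    row
  }))
  structure(list(anova = anova_row, pairwise = pw, family = family,
                 reference = reference, alpha = alpha),
            class = "anova_bonferroni")
}

#' @export
print.anova_bonferroni <- function(x, ...) {
  a <- x$anova
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              a$df1, a$df2, a$statistic, a$p_raw))
  cat(sprintf("Bonferroni pairwise t-tests (%s, family size %d):\n",
              x$family, x$pairwise$family_size[1]))
  print(x$pairwise[, c("comparison", "statistic", "df", "p_raw",
                       "p_adjusted", "significant")], row.names = FALSE)
  invisible(x)
}
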