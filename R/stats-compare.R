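# Paired phase-contrast protocol: Shapiro-Wilk normality gate on the
# paired differences (suitable for cohorts under ~50), then a two-tailed
# paired t test (parametric branch, Cohen's d on the differences) or a
# Wilcoxon signed-rank test (nonparametric branch, Cliff's delta), plus
# the a priori paired-design sample-size calculation via the noncentral t.

#' Normality gate on paired differences
#'
#' Parametric iff the Shapiro-Wilk p-value on the differences is at least
#' `alpha_norm`. Zero-variance differences cannot be tested and are
#' returned as `"degenerate"`.
#'
#' @param differences numeric vector of paired differences, `n >= 3`.
#' @param alpha_norm gate level.
#' @return `"parametric"`, `"nonparametric"` or `"degenerate"`.
#' @export
normality_gate <- function(differences, alpha_norm = 0.05) {
  differences <- differences[!is.na(differences)]
  if (length(differences) < 3L)
    stop("normality gate requires at least 3 paired differences")
  if (sd(differences) == 0) return("degenerate")
  p <- shapiro.test(differences)$p.value
  if (p >= alpha_norm) "parametric" else "nonparametric"
}

#' Cohen's d for paired data
#'
#' The standardized mean difference using the SD of the paired differences
#' as denominator (the matched-pairs d_z convention), or the averaged
#' within-group SD (`denominator = "average"`).
#'
#' @param x,y paired numeric vectors (difference taken as `x - y`).
#' @param denominator `"differences"` (default) or `"average"`.
#' @return signed effect size (NA if the denominator is 0).
#' @export
cohens_d_paired <- function(x, y, denominator = c("differences",
                                                  "average")) {
  denominator <- match.arg(denominator)
  d <- x - y
  s <- if (denominator == "differences") sd(d)
       else sqrt((var(x) + var(y)) / 2)
  if (is.na(s) || s == 0) return(NA_real_)
  mean(d) / s
}

#' Cliff's delta
#'
#' Dominance effect size `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)`;
#' ties contribute zero. Antisymmetric and bounded in `[-1, 1]`.
#'
#' @param x,y numeric vectors (any lengths, nonempty).
#' @return delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("cliffs_delta requires nonempty inputs")
  gt <- outer(x, y, ">")
  lt <- outer(x, y, "<")
  (sum(gt) - sum(lt)) / (length(x) * length(y))
}

#' Qualitative effect-size band
#'
#' Cohen's conventions for d (0.2 / 0.5 / 0.8 for small / medium / large)
#' and the corresponding Cliff's delta bands (0.147 / 0.33 / 0.474). A
#' delta below the medium band is labelled `"high overlap"`, the wording
#' used for such paired-rank contrasts.
#'
#' @param effect_size signed effect size.
#' @param effect_type `"cohen_d"` or `"cliff_delta"`.
#' @return label string.
#' @export
effect_label <- function(effect_size, effect_type = c("cohen_d",
                                                      "cliff_delta")) {
  effect_type <- match.arg(effect_type)
  a <- abs(effect_size)
  if (is.na(a)) return(NA_character_)
  if (effect_type == "cohen_d") {
    if (a < 0.2) "negligible" else if (a < 0.5) "small"
    else if (a < 0.8) "medium" else "large"
  } else {
    if (a < 0.33) "high overlap" else if (a < 0.474) "medium" else "large"
  }
}

#' Paired phase comparison
#'
#' Runs the full gated protocol on one parameter: Shapiro-Wilk gate on the
#' differences, then a two-tailed paired t test with Cohen's d
#' (parametric) or a Wilcoxon signed-rank test with Cliff's delta
#' (nonparametric; exact distribution for n <= 25 without ties, normal
#' approximation with continuity correction otherwise, zero differences
#' dropped). The branch can be forced to reproduce reported analyses.
#'
#' @param baseline_values,phase_values equal-length paired vectors
#'   (`n >= 3` complete pairs).
#' @param parameter,contrast labels carried into the result.
#' @param forced_branch optionally `"parametric"` or `"nonparametric"`.
#' @param alpha_norm gate level for the Shapiro-Wilk test.
#' @param d_denominator Cohen's d convention, see [cohens_d_paired()].
#' @return one-row data.table: `parameter`, `contrast`, `test`, `p_value`,
#'   `effect_size`, `effect_type`, `effect_label`, `n_pairs`, `flag`.
#' @export
paired_compare <- function(baseline_values, phase_values,
                           parameter = NA_character_,
                           contrast = NA_character_,
                           forced_branch = NULL, alpha_norm = 0.05,
                           d_denominator = "differences") {
  stopifnot(length(baseline_values) == length(phase_values))
  ok <- complete.cases(baseline_values, phase_values)
  x <- phase_values[ok]; b <- baseline_values[ok]
  n <- length(x)
  if (n < 3L) stop("paired comparison requires at least 3 complete pairs")
  branch <- if (!is.null(forced_branch)) match.arg(
    forced_branch, c("parametric", "nonparametric"))
    else normality_gate(x - b, alpha_norm)

  if (branch == "degenerate") {
    return(data.table::data.table(
      parameter = parameter, contrast = contrast, test = NA_character_,
      p_value = NA_real_, effect_size = if (all(x == b)) 0 else NA_real_,
      effect_type = NA_character_, effect_label = NA_character_,
      n_pairs = n, flag = "zero_variance_differences"))
  }
  if (branch == "parametric") {
    ht <- t.test(x, b, paired = TRUE)
    es <- cohens_d_paired(x, b, d_denominator)
    data.table::data.table(
      parameter = parameter, contrast = contrast, test = "paired-t",
      p_value = ht$p.value, effect_size = es, effect_type = "cohen_d",
      effect_label = effect_label(es, "cohen_d"), n_pairs = n,
      flag = NA_character_)
  } else {
    d <- x - b
    nz <- d != 0
    p <- if (sum(nz) == 0L) 1 else suppressWarnings(
      wilcox.test(x[nz], b[nz], paired = TRUE,
                  exact = sum(nz) <= 25, correct = TRUE)$p.value)
    es <- cliffs_delta(x, b)
    data.table::data.table(
      parameter = parameter, contrast = contrast,
      test = "wilcoxon-signed-rank", p_value = p, effect_size = es,
      effect_type = "cliff_delta",
      effect_label = effect_label(es, "cliff_delta"), n_pairs = n,
      flag = NA_character_)
  }
}

#' Power of a two-tailed paired t test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' `sqrt(n) * effect_size` and `n - 1` degrees of freedom.
#'
#' @param n number of pairs (>= 2).
#' @param effect_size standardized paired difference (d_z).
#' @param alpha two-tailed level.
#' @return power in `[0, 1]`.
#' @export
paired_t_power <- function(n, effect_size, alpha = 0.05) {
  ncp <- sqrt(n) * effect_size
  tc <- qt(1 - alpha / 2, df = n - 1)
  pt(tc, df = n - 1, ncp = ncp, lower.tail = FALSE) +
    pt(-tc, df = n - 1, ncp = ncp)
}

#' A priori sample size for a paired t test
#'
#' Smallest n such that the two-tailed paired t test achieves the target
#' power at the given standardized effect size.
#'
#' @param effect_size standardized paired difference (> 0).
#' @param alpha two-tailed level in (0, 1).
#' @param power target power in (0, 1).
#' @param n_max scan cap; exceeded -> error (unattainable in practice).
#' @return integer sample size.
#' @export
required_sample_size <- function(effect_size, alpha = 0.05, power = 0.80,
                                 n_max = 1e6) {
  stopifnot(effect_size > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  while (paired_t_power(n, effect_size, alpha) < power) {
    n <- n + 1L
    if (n > n_max) stop("target power unattainable within n_max")
  }
  n
}
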