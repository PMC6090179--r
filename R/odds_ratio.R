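# 2x2 machinery shared by the spontaneous-report ROR and the case-crossover
# OR. Both estimators are (a*d)/(b*c) with a Woolf log-normal confidence
# interval; they differ only in what a row means (reports vs the same patient
# cohort in two windows) and in the signal rule applied on top.

#' 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer counts. For `context = "REPORTS"`,
#'   rows are drug-exposed vs other reports and columns event vs no event.
#'   For `context = "CASE_CROSSOVER"`, both rows describe the same patient
#'   cohort (case window and control window), so `a + b` must equal `c + d`.
#' @param context which design the counts come from.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d,
                              context = c("REPORTS", "CASE_CROSSOVER")) {
  context <- match.arg(context)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("all four cells must be non-negative counts")
  }
  if (context == "CASE_CROSSOVER" && (a + b) != (c + d)) {
    stop("case-crossover table must have a+b == c+d (same cohort in both rows)")
  }
  structure(list(a = a, b = b, c = c, d = d, context = context),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table ", x$context, ">  a=", x$a, " b=", x$b,
      " c=", x$c, " d=", x$d, "\n", sep = "")
  invisible(x)
}

# Haldane-Anscombe: add 0.5 to every cell, only when some cell is zero.
.corrected_cells <- function(t) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (all(cells == 0)) stop("all four cells are zero; odds ratio undefined")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(cells = cells, corrected = corrected)
}

.odds_ratio_ci <- function(cells, z) {
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(estimate = unname(est),
       ci_low = unname(exp(log(est) - z * se)),
       ci_high = unname(exp(log(est) + z * se)))
}

.new_signal_score <- function(t, z, p_value = NULL, p_bonferroni = NULL,
                              joint_rule = FALSE) {
  cc <- .corrected_cells(t)
  or <- .odds_ratio_ci(cc$cells, z)
  is_signal <- or$ci_low > 1
  if (joint_rule) {
    is_signal <- is_signal && !is.null(p_value) && p_value < 0.05
  }
  structure(
    list(estimate = or$estimate, ci_low = or$ci_low, ci_high = or$ci_high,
         p_value = p_value, p_bonferroni = p_bonferroni,
         is_signal = is_signal, corrected = cc$corrected, table = t),
    class = "signal_score"
  )
}

#' Reporting odds ratio of a spontaneous-report table
#'
#' ROR = (a*d)/(b*c) with a Woolf confidence interval
#' `exp(log(ROR) +/- z*sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell triggers
#' the Haldane-Anscombe correction (+0.5 to all four cells) before both the
#' estimate and the interval. A signal is declared when the lower confidence
#' bound exceeds 1.
#'
#' @param t a [contingency_table()] with context `"REPORTS"`.
#' @param z normal quantile for the interval; the default 1.96 gives a 95%
#'   CI.
#' @return A `signal_score`: estimate, `ci_low`, `ci_high`, `is_signal`,
#'   whether the correction was applied, and the input table.
#' @export
ror_score <- function(t, z = 1.96) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$context != "REPORTS") {
    stop("ror_score expects a REPORTS table; use or_score for case-crossover")
  }
  .new_signal_score(t, z)
}

#' Case-crossover odds ratio of a window table
#'
#' Same estimator and interval as [ror_score()], applied to the pooled
#' (unconditional) case-crossover table. The signal rule is joint: the lower
#' 95% confidence bound must exceed 1 *and* the independence p-value must be
#' below 0.05.
#'
#' @param t a [contingency_table()] with context `"CASE_CROSSOVER"`.
#' @param z normal quantile, default 1.96.
#' @param p_method p-value method passed to [outcome_pvalue()].
#' @return A `signal_score` with `p_value` filled in.
#' @export
or_score <- function(t, z = 1.96, p_method = c("auto", "chi2", "fisher")) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$context != "CASE_CROSSOVER") {
    stop("or_score expects a CASE_CROSSOVER table; use ror_score for reports")
  }
  p <- outcome_pvalue(t, method = p_method)
  .new_signal_score(t, z, p_value = as.numeric(p), joint_rule = TRUE)
}

#' @export
print.signal_score <- function(x, ...) {
  cat("<signal_score> estimate ", signif(x$estimate, 4), " [",
      signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "]", sep = "")
  if (!is.null(x$p_value)) cat(", p ", signif(x$p_value, 3), sep = "")
  cat(if (x$is_signal) "  SIGNAL" else "", "\n", sep = "")
  invisible(x)
}

#' Two-sided independence p-value for a 2x2 table
#'
#' Pearson chi-square without continuity correction by default; `"auto"`
#' switches to Fisher's exact test when any expected cell count is below 5
#' (the switch is recorded in the `"method"` attribute of the result).
#' Degenerate column margins (no outcome anywhere, or outcome everywhere)
#' carry no information about association and return p = 1 with a warning.
#'
#' @param t a [contingency_table()].
#' @param method `"auto"`, `"chi2"` or `"fisher"`.
#' @return The p-value, with attribute `"method"` naming the test used.
#' @export
outcome_pvalue <- function(t, method = c("auto", "chi2", "fisher")) {
  stopifnot(inherits(t, "contingency_table"))
  method <- match.arg(method)
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  n <- sum(m)
  if (n == 0 || any(colSums(m) == 0) || any(rowSums(m) == 0)) {
    warning("degenerate margin; p-value set to 1")
    return(structure(1, method = "degenerate"))
  }
  expected <- outer(rowSums(m), colSums(m)) / n
  used <- method
  if (method == "auto") used <- if (any(expected < 5)) "fisher" else "chi2"
  p <- if (used == "fisher") {
    stats::fisher.test(m)$p.value
  } else {
    stats::chisq.test(m, correct = FALSE)$p.value
  }
  structure(unname(p), method = used)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param m number of comparisons, at least 1.
#' @return `min(1, p * m)`, elementwise.
#' @export
bonferroni <- function(p, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a single value >= 1")
  pmin(1, p * m)
}
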