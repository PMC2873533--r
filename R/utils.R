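# Structured error conditions so callers can route failures (NoAmplification,
# NoCt, EfficiencyUndetermined, ...) without string matching.
sod_error <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "sodpcr_error", "error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Chi-squared and normal critical values
#'
#' Critical values used by the outlier tests, computed from the distribution
#' functions rather than hard-coded. At `alpha = 0.05` these reproduce the
#' conventional thresholds 3.84 (1 df, KOD), 7.81 (3 df, SOD) and the
#' two-sided normal bound 1.96.
#'
#' @param df degrees of freedom (1 for KOD, 3 for SOD).
#' @param alpha significance level in (0, 0.5].
#' @return Upper-tail critical value.
#' @examples
#' chi2_critical(3)          # 7.814728
#' chi2_critical(1)          # 3.841459
#' normal_critical()         # 1.959964
#' @export
chi2_critical <- function(df, alpha = 0.05) {
  stopifnot(is_scalar_number(alpha), alpha > 0, alpha <= 0.5, df >= 1)
  qchisq(1 - alpha, df = df)
}

#' @rdname chi2_critical
#' @export
normal_critical <- function(alpha = 0.05) {
  stopifnot(is_scalar_number(alpha), alpha > 0, alpha <= 0.5)
  qnorm(1 - alpha / 2)
}

#' Fold difference accumulated by an efficiency gap
#'
#' The Ct method's vulnerability in closed form: two reactions whose
#' per-cycle amplification factors differ by ratio `e1/e2` diverge by
#' `(e1/e2)^cycles` in product after `cycles` cycles. A 5\% efficiency gap
#' (ratio 1.05) already exceeds three-fold after 25 cycles.
#'
#' @param e1,e2 per-cycle amplification factors (2 = perfect doubling).
#' @param cycles number of exponential cycles.
#' @return The fold difference in accumulated product.
#' @examples
#' efficiency_fold_difference(2 * 1.05, 2, 25)  # about 3.39
#' @export
efficiency_fold_difference <- function(e1, e2, cycles) {
  stopifnot(e1 > 0, e2 > 0, cycles >= 0)
  (e1 / e2)^cycles
}
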