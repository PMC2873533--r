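#' Fit-point threshold cycle
#'
#' Fractional cycle at which the (background-subtracted) trace first crosses
#' the fluorescence threshold from below, by linear interpolation between
#' the flanking cycles. The instrument-style default threshold is 0.4.
#'
#' @param run an [amp_run()].
#' @param threshold positive fluorescence threshold.
#' @return Fractional cycle Ct. Raises `sod_no_ct` when the trace never
#'   reaches the threshold (total amplification failure) and
#'   `sod_baseline_error` when the trace already starts above it.
#' @examples
#' r <- amp_run("a", 1:10, c(0, 0, 0, 0.1, 0.3, 0.5, 1, 2, 3, 3.5))
#' ct_fit_point(r, 0.4)  # 5.5
#' @export
ct_fit_point <- function(run, threshold = 0.4) {
  stopifnot(inherits(run, "amp_run"), is_scalar_number(threshold),
            threshold > 0)
  f <- run$fluorescence
  x <- as.numeric(run$cycles)
  if (f[1] >= threshold)
    sod_error("sod_baseline_error", sprintf(
      "run '%s': fluorescence already above threshold at cycle %d",
      run$run_id, run$cycles[1]))
  hits <- which(f[-1] >= threshold & f[-length(f)] < threshold)
  if (length(hits) == 0L)
    sod_error("sod_no_ct", sprintf(
      "run '%s': trace never crosses threshold %.3g (max %.3g)",
      run$run_id, threshold, max(f)))
  i <- hits[1]
  x[i] + (threshold - f[i]) / (f[i + 1] - f[i]) * (x[i + 1] - x[i])
}

#' Standard curve: Ct versus log10 input copies
#'
#' Ordinary least-squares regression `Ct = intercept + slope * log10_input`
#' over the standard runs of a dilution series. For a perfect doubling
#' assay the slope is `-1/log10(2) = -3.32` cycles per decade; the implied
#' overall efficiency is `E = 10^(-1/slope)`.
#'
#' @param ct numeric vector of threshold cycles.
#' @param log10_input numeric vector, log10 of known input copies.
#' @param threshold the fluorescence threshold the Cts were read at
#'   (recorded for provenance).
#' @return A `standard_curve`: list with `intercept`, `slope`, `r_squared`,
#'   `efficiency_from_slope`, `threshold`, `n_runs`.
#' @export
build_standard_curve <- function(ct, log10_input, threshold = 0.4) {
  keep <- is.finite(ct) & is.finite(log10_input)
  ct <- ct[keep]; log10_input <- log10_input[keep]
  if (length(unique(log10_input)) < 2L)
    sod_error("sod_degenerate_curve",
              "standard curve needs at least 2 distinct input amounts")
  fit <- lm(ct ~ log10_input)
  slope <- unname(coef(fit)[2])
  if (slope >= 0)
    warning("standard-curve slope is non-negative; dilution series suspect")
  eff <- 10^(-1 / slope)
  if (!is.na(eff) && (eff <= 1 || eff > 2.2))
    warning(sprintf(
      "slope-implied efficiency %.3f outside plausible range (1, 2.2]", eff))
  tss <- sum((ct - mean(ct))^2)
  r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else NA_real_
  structure(
    list(intercept = unname(coef(fit)[1]), slope = slope,
         r_squared = r2,
         efficiency_from_slope = eff, threshold = threshold,
         n_runs = length(ct)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.3f %+.4f * log10(N)  (R2 %.4f, E %.3f, n %d)\n",
    x$intercept, x$slope, x$r_squared, x$efficiency_from_slope, x$n_runs))
  invisible(x)
}

#' Copy number from a threshold cycle
#'
#' Inverts the standard curve: `Nob = 10^((ct - intercept)/slope)`.
#' Strictly decreasing in `ct` for a valid (negative-slope) curve.
#'
#' @param ct threshold cycle(s).
#' @param curve a [build_standard_curve()] result.
#' @return Estimated starting copies (vectorized over `ct`).
#' @export
estimate_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Quantification-residual confidence interval
#'
#' Per-run residual `Log(Nob/Nexp) = log10(Nob) - log10(Nexp)` over the
#' standard runs; its mean is ~0 and its spread sets the 95% band
#' (`mean +/- 1.96 * SD`, SD with denominator n-1) that defines
#' ground-truth quantification outliers.
#'
#' @param nob observed copies (from [estimate_copies()]).
#' @param nexp expected (known input) copies, same length.
#' @return A `residual_ci`: list with `mean_resid`, `sigma_resid`, `lower`,
#'   `upper`, `n`.
#' @export
residual_ci <- function(nob, nexp) {
  stopifnot(length(nob) == length(nexp))
  keep <- is.finite(nob) & is.finite(nexp) & nob > 0 & nexp > 0
  r <- log10(nob[keep]) - log10(nexp[keep])
  if (length(r) < 10L)
    sod_error("sod_too_few_points", sprintf(
      "residual CI needs >= 10 standard runs; got %d", length(r)))
  s <- sd(r)
  if (s == 0)
    warning("all residuals identical; confidence interval is degenerate")
  z <- normal_critical(0.05)
  structure(
    list(mean_resid = mean(r), sigma_resid = s,
         lower = mean(r) - z * s, upper = mean(r) + z * s,
         n = length(r)),
    class = "residual_ci")
}

#' @export
print.residual_ci <- function(x, ...) {
  cat(sprintf(
    "<residual_ci> Log(Nob/Nexp): mean %.4f, sigma %.4f, 95%% CI [%.4f, %.4f] (n %d)\n",
    x$mean_resid, x$sigma_resid, x$lower, x$upper, x$n))
  invisible(x)
}

#' Ground-truth outlier label from a quantification residual
#'
#' A run is a true quantification outlier when its `Log(Nob/Nexp)` falls
#' strictly outside the 95% band; the bounds themselves are inclusive
#' (a residual exactly on the bound is not an outlier).
#'
#' @param resid residual(s) `log10(Nob) - log10(Nexp)`.
#' @param ci a [residual_ci()] result.
#' @return Logical vector, `TRUE` for true outliers (`NA` propagates).
#' @export
truth_label <- function(resid, ci) {
  stopifnot(inherits(ci, "residual_ci"))
  if (ci$sigma_resid == 0)
    sod_error("sod_degenerate_ci",
              "degenerate residual CI; cannot label outliers")
  resid < ci$lower | resid > ci$upper
}
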