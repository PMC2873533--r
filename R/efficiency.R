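#' Per-run PCR efficiency from the window of linearity
#'
#' Estimates the per-cycle amplification factor from the exponential phase:
#' among contiguous windows of `window_min` to `window_max` cycles whose
#' readings are all positive, above `floor_frac` of the plateau and below
#' `ceiling_frac` of the plateau, the window maximizing the R-squared of
#' `log10(F)` versus cycle is selected (ties broken toward the wider
#' window, then the earlier start). When the trace crosses the
#' quantification threshold, only windows anchored at the crossing are
#' considered -- the crossing must lie between one cycle before the window
#' start and the window end -- so the efficiency is read where
#' quantification happens (the noise floor can sit fractionally above the
#' threshold itself, hence the one-cycle grace below the window).
#' Efficiency is `10^slope` of that regression (2 = perfect doubling).
#'
#' @param run an [amp_run()].
#' @param window_min,window_max window width bounds, in cycles.
#' @param floor_frac,ceiling_frac eligible fluorescence band as fractions
#'   of the plateau (maximum reading).
#' @param threshold quantification threshold the window should span; set
#'   `NULL` to drop the constraint.
#' @return An `efficiency_estimate`: list with `run_id`, `efficiency`,
#'   `window_start`, `window_end`, `window_r_squared`. Raises
#'   `sod_efficiency_undetermined` when fewer than `window_min` eligible
#'   readings exist.
#' @examples
#' r <- amp_run("e", 1:30, pmin(0.001 * 2^(1:30), 40))
#' window_of_linearity(r)$efficiency  # 2
#' @export
window_of_linearity <- function(run, window_min = 4L, window_max = 6L,
                                floor_frac = 0.01, ceiling_frac = 0.8,
                                threshold = 0.4) {
  stopifnot(inherits(run, "amp_run"), window_min >= 2L,
            window_max >= window_min)
  f <- run$fluorescence
  x <- as.numeric(run$cycles)
  plateau <- max(f)
  ok <- f > 0 & f > floor_frac * plateau & f < ceiling_frac * plateau
  if (sum(ok) < window_min)
    sod_error("sod_efficiency_undetermined", sprintf(
      "run '%s': only %d eligible readings for the window of linearity",
      run$run_id, sum(ok)))

  cand <- list()
  for (w in seq(window_min, window_max)) {
    for (s in seq_len(length(f) - w + 1L)) {
      idx <- s:(s + w - 1L)
      if (!all(ok[idx])) next
      lf <- log10(f[idx])
      xi <- x[idx]
      slope <- cov(xi, lf) / var(xi)
      r2 <- cor(xi, lf)^2
      cand[[length(cand) + 1L]] <- c(start = s, width = w,
                                     slope = slope, r2 = r2)
    }
  }
  if (length(cand) == 0L)
    sod_error("sod_efficiency_undetermined", sprintf(
      "run '%s': no eligible contiguous window of width %d-%d",
      run$run_id, window_min, window_max))
  cand <- do.call(rbind, cand)

  if (!is.null(threshold)) {
    ct <- tryCatch(ct_fit_point(run, threshold), error = function(e) NULL)
    if (!is.null(ct)) {
      spans <- x[cand[, "start"]] - 1 <= ct &
        x[cand[, "start"] + cand[, "width"] - 1L] >= ct
      if (any(spans)) cand <- cand[spans, , drop = FALSE]
    }
  }
  best_r2 <- max(cand[, "r2"])
  top <- cand[cand[, "r2"] >= best_r2 - 1e-12, , drop = FALSE]
  top <- top[order(-top[, "width"], top[, "start"]), , drop = FALSE]
  pick <- top[1, ]
  structure(
    list(run_id = run$run_id, efficiency = 10^unname(pick["slope"]),
         window_start = run$cycles[pick["start"]],
         window_end = run$cycles[pick["start"] + pick["width"] - 1L],
         window_r_squared = unname(pick["r2"])),
    class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf(
    "<efficiency_estimate '%s'> E = %.4f, window %d-%d (R2 %.4f)\n",
    x$run_id, x$efficiency, x$window_start, x$window_end,
    x$window_r_squared))
  invisible(x)
}

#' Kinetic outlier detection by efficiency (KOD)
#'
#' z-test of a sample's PCR efficiency against the standard-curve
#' efficiency distribution: `z = (x_eff - mu_eff)/sigma_eff` with the mean
#' and SD (denominator n-1) taken over the reference efficiencies.
#' `z^2` is chi-squared with 1 df under the null, so a run is an outlier
#' when `z^2` exceeds the critical value (3.84 at `alpha = 0.05`,
#' equivalently `|z| > 1.96`).
#'
#' @param x_eff test-sample efficiency (or vector of them).
#' @param ref_effs reference (standard-run) efficiencies, length >= 3 with
#'   positive SD.
#' @param alpha significance level.
#' @return data frame with columns `x_eff`, `z`, `chi2`, `is_outlier`
#'   (one row per element of `x_eff`).
#' @export
kod_test <- function(x_eff, ref_effs, alpha = 0.05) {
  ref_effs <- ref_effs[is.finite(ref_effs)]
  if (length(ref_effs) < 3L)
    sod_error("sod_degenerate_reference",
              "KOD reference needs >= 3 efficiencies")
  s <- sd(ref_effs)
  if (s == 0)
    sod_error("sod_degenerate_reference",
              "KOD reference efficiencies have zero SD")
  z <- (x_eff - mean(ref_effs)) / s
  chi2 <- z^2
  data.frame(x_eff = x_eff, z = z, chi2 = chi2,
             is_outlier = !is.na(chi2) & chi2 > chi2_critical(1, alpha))
}
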