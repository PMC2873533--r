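#' Run the full SOD/KOD quality-control pipeline on a plate
#'
#' End-to-end analysis: fits the Richards model to every run, builds the
#' shape reference and the efficiency reference from the standard runs,
#' determines fit-point Cts and the standard curve, derives quantification
#' residuals and their 95% CI (the ground-truth outlier labels), applies
#' the SOD and KOD tests to every run, and scores both methods against the
#' truth labels per inhibitor stratum.
#'
#' Runs the Richards model cannot fit are by definition shape-aberrant:
#' they are reported as SOD outliers with `d2 = Inf` and a reason code,
#' and excluded from the reference. Symmetrically, runs whose efficiency
#' is undetermined are reported as KOD outliers with a reason code.
#'
#' @param plate an `amp_plate` with at least 10 standard runs carrying
#'   `log10_input`.
#' @param threshold quantification fluorescence threshold.
#' @param sod_alpha,kod_alpha significance levels of the two tests.
#' @param window_min,window_max efficiency window bounds (cycles).
#' @param min_plateau_frac fraction of the reference plateau below which a
#'   trace is declared NoAmplification.
#' @param verbose emit per-stage count messages?
#' @return A `sod_analysis` list: `fits`, `quantification`, `kod`, `sod`,
#'   `evaluation`, `reference`, `standard_curve`, `residual_ci`.
#' @export
analyze_plate <- function(plate, threshold = 0.4, sod_alpha = 0.05,
                          kod_alpha = 0.05, window_min = 4L,
                          window_max = 6L, min_plateau_frac = 0.1,
                          verbose = TRUE) {
  stopifnot(inherits(plate, "amp_plate"))
  say <- function(...) if (verbose) message(sprintf(...))
  roles <- vapply(plate, `[[`, character(1), "role")
  std_ids <- names(plate)[roles == "standard"]
  if (length(std_ids) == 0L)
    sod_error("sod_degenerate_reference",
              "no standard runs; reference unbuildable")

  ref_plateau <- stats::median(vapply(
    unclass(plate)[std_ids],
    function(r) max(r$fluorescence) - min(r$fluorescence), numeric(1)))
  fits <- fit_plate(plate, ref_plateau = ref_plateau,
                    min_plateau_frac = min_plateau_frac)
  say("fitted %d/%d runs (%d not converged or not amplified)",
      sum(fits$converged), nrow(fits), sum(!fits$converged))

  is_std <- fits$role == "standard"
  std_ok <- is_std & fits$converged
  if (sum(is_std & !fits$converged) > 0L)
    say("excluded %d non-converged standard run(s) from the reference",
        sum(is_std & !fits$converged))
  reference <- build_reference(fits[std_ok, c("Fmax", "Yf", "m")])

  # --- quantification -----------------------------------------------------
  ct <- rep(NA_real_, nrow(fits))
  ct_reason <- rep("ok", nrow(fits))
  for (i in seq_len(nrow(fits))) {
    v <- tryCatch(ct_fit_point(plate[[fits$run_id[i]]], threshold),
                  error = function(e) e)
    if (inherits(v, "error")) {
      ct_reason[i] <- if (inherits(v, "sod_no_ct")) "no_ct" else "baseline"
    } else ct[i] <- v
  }
  say("%d run(s) without a threshold crossing", sum(ct_reason == "no_ct"))
  curve <- build_standard_curve(ct[is_std], fits$log10_input[is_std],
                                threshold = threshold)
  log10_nob <- log10(estimate_copies(ct, curve))
  resids <- log10_nob - fits$log10_input
  ci <- residual_ci(10^log10_nob[is_std], 10^fits$log10_input[is_std])
  is_true <- ifelse(is.finite(resids), truth_label(resids, ci), NA)
  # a run with known input but no Ct failed quantification outright
  is_true[!is.na(fits$log10_input) & !is.finite(resids)] <- TRUE
  quantification <- data.frame(
    run_id = fits$run_id, ct = ct, log10_nob = log10_nob,
    log10_nexp = fits$log10_input, resid = resids,
    is_true_outlier = is_true, reason = ct_reason,
    stringsAsFactors = FALSE)

  # --- KOD ----------------------------------------------------------------
  eff <- rep(NA_real_, nrow(fits))
  wstart <- wend <- rep(NA_integer_, nrow(fits))
  wr2 <- rep(NA_real_, nrow(fits))
  kod_reason <- rep("ok", nrow(fits))
  for (i in seq_len(nrow(fits))) {
    e <- tryCatch(
      window_of_linearity(plate[[fits$run_id[i]]], window_min, window_max,
                          threshold = threshold),
      error = function(e) e)
    if (inherits(e, "error")) {
      kod_reason[i] <- "efficiency_undetermined"
    } else {
      eff[i] <- e$efficiency; wstart[i] <- e$window_start
      wend[i] <- e$window_end; wr2[i] <- e$window_r_squared
    }
  }
  ref_effs <- eff[is_std & kod_reason == "ok"]
  kod_stats <- kod_test(eff, ref_effs, alpha = kod_alpha)
  kod <- data.frame(
    run_id = fits$run_id, efficiency = eff, window_start = wstart,
    window_end = wend, window_r2 = wr2, z = kod_stats$z,
    chi2 = kod_stats$chi2,
    kod_outlier = kod_stats$is_outlier | kod_reason != "ok",
    reason = kod_reason, stringsAsFactors = FALSE)
  say("KOD: %d outlier(s), of which %d with undetermined efficiency",
      sum(kod$kod_outlier), sum(kod_reason != "ok"))

  # --- SOD ----------------------------------------------------------------
  d2 <- rep(Inf, nrow(fits))
  sod_outlier <- rep(TRUE, nrow(fits))
  conv <- fits$converged
  if (any(conv)) {
    st <- sod_test(fits[conv, c("Fmax", "Yf", "m")], reference,
                   alpha = sod_alpha)
    d2[conv] <- st$d2
    sod_outlier[conv] <- st$is_outlier
  }
  sod <- data.frame(
    run_id = fits$run_id, Fmax = fits$Fmax, Yf = fits$Yf, m = fits$m,
    d2 = d2, sod_outlier = sod_outlier,
    reason = ifelse(conv, "ok", fits$reason), stringsAsFactors = FALSE)
  say("SOD: %d outlier(s), of which %d unfittable", sum(sod$sod_outlier),
      sum(!conv))

  # --- evaluation (runs with a truth label only) --------------------------
  has_truth <- !is.na(quantification$is_true_outlier)
  strat <- ifelse(is.na(fits$inhibitor), "none", fits$inhibitor)
  evaluation <- rbind(
    confusion(sod$sod_outlier[has_truth],
              quantification$is_true_outlier[has_truth],
              stratum = strat[has_truth], method = "SOD",
              run_id = fits$run_id[has_truth]),
    confusion(kod$kod_outlier[has_truth],
              quantification$is_true_outlier[has_truth],
              stratum = strat[has_truth], method = "KOD",
              run_id = fits$run_id[has_truth]))

  structure(
    list(fits = fits, quantification = quantification, kod = kod,
         sod = sod, evaluation = evaluation, reference = reference,
         standard_curve = curve, residual_ci = ci),
    class = "sod_analysis")
}

#' @export
print.sod_analysis <- function(x, ...) {
  cat(sprintf("<sod_analysis> %d runs, reference n = %d\n",
              nrow(x$fits), x$reference$n_ref))
  print(x$standard_curve)
  print(x$residual_ci)
  cat("evaluation (stratum 'all'):\n")
  print(x$evaluation[x$evaluation$stratum == "all", ], row.names = FALSE)
  invisible(x)
}

#' Write pipeline results as CSV files
#'
#' Emits `fits.csv`, `quantification.csv`, `kod.csv`, `sod.csv` and
#' `evaluation.csv` into a directory.
#'
#' @param analysis a [analyze_plate()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "sod_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("fits", "quantification", "kod", "sod", "evaluation"))
    write.csv(analysis[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  invisible(dir)
}
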