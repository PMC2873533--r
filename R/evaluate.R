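#' Confusion-matrix evaluation of outlier calls
#'
#' Scores a method's outlier calls against the quantification ground truth
#' (`Log(Nob/Nexp)` outside its 95% CI). TP: flagged and truly out;
#' FP: flagged but within the CI; TN: not flagged and within; FN: missed.
#' Sensitivity is `TP/(TP+FN)`, specificity `TN/(TN+FP)`; an undefined
#' ratio (zero denominator) is reported as `NA`, not 0.
#'
#' @param calls logical vector of outlier calls.
#' @param truth logical vector of true-outlier labels, same length.
#' @param stratum optional character vector (e.g. inhibitor name) splitting
#'   the report into strata; an `"all"` aggregate row is always emitted.
#' @param method label recorded in the report (e.g. `"SOD"`, `"KOD"`).
#' @param run_id optional ids used in error messages for missing labels.
#' @return data frame: `stratum, method, tp, fp, tn, fn, sensitivity,
#'   specificity`.
#' @export
confusion <- function(calls, truth, stratum = NULL, method = "SOD",
                      run_id = NULL) {
  stopifnot(length(calls) == length(truth))
  if (anyNA(calls) || anyNA(truth)) {
    bad <- which(is.na(calls) | is.na(truth))
    lab <- if (!is.null(run_id)) paste(run_id[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    sod_error("sod_missing_labels",
              sprintf("missing call or truth label for run(s): %s", lab))
  }
  one <- function(cl, tr, name) {
    tp <- sum(cl & tr); fp <- sum(cl & !tr)
    tn <- sum(!cl & !tr); fn <- sum(!cl & tr)
    data.frame(
      stratum = name, method = method, tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- one(calls, truth, "all")
  if (!is.null(stratum)) {
    stopifnot(length(stratum) == length(calls))
    for (s in unique(stratum)) {
      i <- stratum == s
      out <- rbind(out, one(calls[i], truth[i], s))
    }
  }
  rownames(out) <- NULL
  out
}
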