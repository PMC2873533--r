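as_fingerprint_matrix <- function(fingerprints) {
  if (is.data.frame(fingerprints)) {
    stopifnot(all(c("Fmax", "Yf", "m") %in% names(fingerprints)))
    y <- as.matrix(fingerprints[, c("Fmax", "Yf", "m")])
  } else if (inherits(fingerprints, "shape_fingerprint")) {
    y <- matrix(unlist(fingerprints[c("Fmax", "Yf", "m")]), nrow = 1,
                dimnames = list(fingerprints$run_id, c("Fmax", "Yf", "m")))
  } else if (is.list(fingerprints)) {
    y <- t(vapply(fingerprints,
                  function(fp) unlist(fp[c("Fmax", "Yf", "m")]),
                  numeric(3)))
    colnames(y) <- c("Fmax", "Yf", "m")
  } else if (is.matrix(fingerprints)) {
    y <- fingerprints
    colnames(y) <- c("Fmax", "Yf", "m")
  } else stop("cannot interpret fingerprints")
  y
}

#' Build the multivariate shape reference from standard runs
#'
#' Mean vector and sample variance-covariance matrix (denominator n-1) of
#' the shape fingerprints `(Fmax, Yf, m)` of the standard-curve runs. This
#' is the null distribution every test run is compared against. The
#' asymptotic chi-squared calibration of the distance test assumes a
#' reasonably large reference; a warning is issued below 30 runs.
#'
#' @param fingerprints fingerprints of converged standard fits: a data
#'   frame with columns `Fmax, Yf, m` (e.g. from [fit_plate()]), a list of
#'   [shape_fingerprint()] objects, or a numeric matrix.
#' @return A `sod_reference`: list with `mu` (3-vector), `sigma` (3x3),
#'   `n_ref`, `parameter_order`.
#' @export
build_reference <- function(fingerprints) {
  y <- as_fingerprint_matrix(fingerprints)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n <- nrow(y)
  if (n < 10L)
    sod_error("sod_degenerate_reference", sprintf(
      "reference needs >= 10 converged standard fits; got %d", n))
  if (n < 30L)
    warning(sprintf(
      "only %d reference runs; asymptotic chi-squared calibration is rough below 30",
      n))
  mu <- colMeans(y)
  sigma <- cov(y)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12)
    sod_error("sod_singular_reference",
              "reference covariance is singular or near-singular; add replicates or jitter")
  structure(
    list(mu = mu, sigma = sigma, n_ref = n,
         parameter_order = c("Fmax", "Yf", "m")),
    class = "sod_reference")
}

#' @export
print.sod_reference <- function(x, ...) {
  cat(sprintf("<sod_reference> n = %d\n  mu: Fmax %.3f, Yf %.3f, m %.3f\n",
              x$n_ref, x$mu["Fmax"], x$mu["Yf"], x$mu["m"]))
  invisible(x)
}

# Squared Mahalanobis distance via Cholesky backsolve (numerically stable;
# never forms the explicit inverse). y: n x 3 matrix.
mahalanobis_d2 <- function(y, mu, sigma) {
  R <- chol(sigma)
  z <- backsolve(R, t(y) - mu, transpose = TRUE)
  colSums(z^2)
}

#' Shape-based outlier test (SOD)
#'
#' Squared Mahalanobis distance of a run's shape fingerprint from the
#' standard reference, `d2 = (y - mu)' Sigma^{-1} (y - mu)`. Under
#' multivariate normality of the reference, `d2` is asymptotically
#' chi-squared with 3 degrees of freedom; a run is flagged when `d2`
#' exceeds the critical value (7.81 at `alpha = 0.05`).
#'
#' @param fingerprints one or more fingerprints (see [build_reference()]
#'   for accepted forms).
#' @param ref a [build_reference()] result.
#' @param alpha significance level.
#' @return data frame with columns `Fmax`, `Yf`, `m`, `d2`, `is_outlier`
#'   (and `run_id` when available).
#' @export
sod_test <- function(fingerprints, ref, alpha = 0.05) {
  stopifnot(inherits(ref, "sod_reference"))
  y <- as_fingerprint_matrix(fingerprints)
  if (any(!is.finite(y)))
    sod_error("sod_bad_fingerprint", "non-finite shape fingerprint")
  d2 <- mahalanobis_d2(y, ref$mu, ref$sigma)
  out <- data.frame(Fmax = y[, "Fmax"], Yf = y[, "Yf"], m = y[, "m"],
                    d2 = d2, is_outlier = d2 > chi2_critical(3, alpha))
  if (!is.null(rownames(y))) out <- cbind(run_id = rownames(y), out)
  rownames(out) <- NULL
  out
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests a parameter vector against the normal distribution with the
#' sample's own mean and SD, reporting the instrument-software convention:
#' `Z = sqrt(n) * D` and the asymptotic Kolmogorov p-value.
#'
#' @param values numeric vector, n >= 8, positive SD.
#' @return list with `ks_z`, `D`, `p`, `n`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8L)
    sod_error("sod_too_few_points", "K-S normality check needs n >= 8")
  if (sd(values) == 0)
    sod_error("sod_degenerate_reference", "zero variance; K-S undefined")
  kt <- suppressWarnings(
    ks.test(values, "pnorm", mean(values), sd(values), exact = FALSE))
  D <- unname(kt$statistic)
  list(ks_z = sqrt(n) * D, D = D, p = kt$p.value, n = n)
}

#' Correlation t-test of a shape parameter against input amount
#'
#' Pearson correlation of a fitted parameter with log10 input copies and
#' the t-test of its significance, `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' with n-2 df (two-sided). Used to verify that the shape fingerprint is
#' concentration-independent.
#'
#' @param values parameter values, one per run.
#' @param log10_inputs log10 input copies, same length.
#' @return list with `r`, `r2`, `t`, `p`, `n`.
#' @export
correlation_t_test <- function(values, log10_inputs) {
  stopifnot(length(values) == length(log10_inputs))
  keep <- is.finite(values) & is.finite(log10_inputs)
  values <- values[keep]; log10_inputs <- log10_inputs[keep]
  n <- length(values)
  if (n < 3L)
    sod_error("sod_too_few_points", "correlation t-test needs n >= 3")
  if (sd(values) == 0 || sd(log10_inputs) == 0)
    sod_error("sod_degenerate_reference",
              "constant vector; correlation undefined")
  r <- cor(values, log10_inputs)
  tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.xmin))
  list(r = r, r2 = r^2, t = tt, p = 2 * pt(-abs(tt), df = n - 2), n = n)
}

#' Multivariate-normality diagnostic for the reference set
#'
#' Chi-squared Q-Q diagnostic of the reference fingerprints: each run's
#' squared Mahalanobis distance from the reference mean, sorted and paired
#' with chi-squared(3) quantiles at plotting positions `(i - 0.5)/n`. A
#' Q-Q correlation near 1 supports the multivariate-normal assumption
#' behind the SOD calibration. With the n-1 covariance denominator the
#' reference distances satisfy `sum(d2) = 3 * (n - 1)` exactly.
#'
#' @param fingerprints the reference fingerprints (see [build_reference()]).
#' @param ref the reference built from those same fingerprints.
#' @return list with `table` (data frame `d2`, `chi2_quantile`, sorted
#'   ascending) and `qq_cor`.
#' @export
multivariate_normality_d2 <- function(fingerprints, ref) {
  stopifnot(inherits(ref, "sod_reference"))
  y <- as_fingerprint_matrix(fingerprints)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  d2 <- sort(mahalanobis_d2(y, ref$mu, ref$sigma))
  n <- length(d2)
  q <- qchisq((seq_len(n) - 0.5) / n, df = 3)
  list(table = data.frame(d2 = d2, chi2_quantile = q),
       qq_cor = cor(d2, q))
}
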