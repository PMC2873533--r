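#' Five-parameter Richards amplification model
#'
#' The sigmoid used to parameterize amplification curves:
#' \deqn{F(x) = F_b + F_{max} (1 + e^{-(x - c)/b})^{-d}}
#' `d = 1` recovers the symmetric logistic; `d > 1` skews the approach to
#' plateau, the "Richards-type" kinetic typical of inhibited reactions.
#' The curve rises monotonically from `Fb` (as `x -> -Inf`) to `Fb + Fmax`.
#'
#' @param x cycle number(s); may be fractional.
#' @param Fmax maximal fluorescence above background (> 0).
#' @param b scale parameter, in cycles (> 0).
#' @param c location parameter, in cycles.
#' @param d Richards asymmetry exponent (> 0); 1 = logistic.
#' @param Fb background fluorescence.
#' @return Model fluorescence at `x` (vectorized over `x`).
#' @examples
#' richards_model(20, Fmax = 40, b = 2, c = 20, d = 2, Fb = 2)  # 12
#' @export
richards_model <- function(x, Fmax, b, c, d = 1, Fb = 0) {
  stopifnot(b > 0, d > 0)
  z <- -(x - c) / b
  z <- pmin(pmax(z, -700), 700)            # overflow guard
  # log(1 + e^z) without overflow; for large z, log1p(e^z) ~ z
  lse <- ifelse(z > 35, z, log1p(exp(z)))
  Fb + Fmax * exp(-d * lse)
}

default_fit_control <- function() {
  list(min_points = 8L, flat_floor = 1e-6, max_iter = 500L,
       b_bounds = c(0.1, 20), d_bounds = c(0.05, 20))
}

#' Fit the Richards function to one amplification run
#'
#' Unweighted least-squares estimation of `(Fmax, Fb, b, c, d)` by the
#' Levenberg-Marquardt algorithm (via [minpack.lm::nls.lm()]). Starting
#' values: `Fb` from the mean of the first five readings, `Fmax` from the
#' observed range, `c` at the half-maximum crossing, `b = 2`, `d = 1` --
#' which places the optimizer in the right basin for any sigmoid trace.
#' Box constraints keep the exponent well-conditioned
#' (`b` in \[0.1, 20\], `d` in \[0.05, 20\], `Fmax` in (0, 10 x range],
#' `c` in \[1, 2C\]); an estimate pinned at a bound, like an optimizer
#' failure, is reported as `converged = FALSE` rather than an error.
#'
#' @param run an [amp_run()].
#' @param control list overriding the default fit-control entries
#'   (`min_points`, `flat_floor`, `max_iter`, `b_bounds`, `d_bounds`).
#' @return A `richards_fit`: list with `run_id`, estimates `Fmax, Fb, b, c,
#'   d`, `converged`, residual sum of squares `rss`, and `n_points`.
#'   A flat trace (range below `flat_floor`) raises a `sod_no_amplification`
#'   error.
#' @export
fit_richards <- function(run, control = list()) {
  stopifnot(inherits(run, "amp_run"))
  ctl <- modifyList(default_fit_control(), control)
  x <- as.numeric(run$cycles)
  f <- run$fluorescence
  if (length(x) < ctl$min_points)
    sod_error("sod_too_few_points", sprintf(
      "run '%s': %d readings, need at least %d",
      run$run_id, length(x), ctl$min_points))
  rng <- max(f) - min(f)
  if (rng < ctl$flat_floor)
    sod_error("sod_no_amplification", sprintf(
      "run '%s': flat trace (range %.3g below floor %.3g)",
      run$run_id, rng, ctl$flat_floor))

  Fb0 <- mean(f[seq_len(min(5L, length(f)))])
  Fmax0 <- max(f) - Fb0
  if (Fmax0 <= 0) Fmax0 <- rng / 2
  above <- which(f - Fb0 >= Fmax0 / 2)
  c0 <- if (length(above)) x[above[1]] else stats::median(x)
  lower <- c(Fmax = 1e-9, Fb = -Inf, b = ctl$b_bounds[1],
             c = 1, d = ctl$d_bounds[1])
  upper <- c(Fmax = 10 * rng, Fb = Inf, b = ctl$b_bounds[2],
             c = 2 * max(x), d = ctl$d_bounds[2])
  start <- list(Fmax = min(max(Fmax0, 1e-6), 10 * rng), Fb = Fb0,
                b = 2, c = min(max(c0, 1), 2 * max(x)), d = 1)

  residual_fun <- function(p)
    f - richards_model(x, p["Fmax"], p["b"], p["c"], p["d"], p["Fb"])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start), lower = lower, upper = upper,
      fn = residual_fun,
      control = minpack.lm::nls.lm.control(
        maxiter = ctl$max_iter, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)

  if (is.null(fit) || !fit$info %in% 1:3 || any(!is.finite(fit$par))) {
    est <- if (is.null(fit)) rep(NA_real_, 5) else fit$par
    names(est) <- names(start)
    out <- list(run_id = run$run_id, Fmax = unname(est["Fmax"]),
                Fb = unname(est["Fb"]), b = unname(est["b"]),
                c = unname(est["c"]), d = unname(est["d"]),
                converged = FALSE,
                rss = if (is.null(fit)) NA_real_ else fit$deviance,
                n_points = length(x))
    return(structure(out, class = "richards_fit"))
  }
  est <- fit$par
  # an estimate pinned at a box bound is not a trustworthy interior optimum
  tol <- 1e-6 * pmax(abs(est), 1)
  bounded <- c("Fmax", "b", "c", "d")
  at_bound <- any(est[bounded] <= lower[bounded] + tol[bounded]) ||
    any(est[bounded] >= upper[bounded] - tol[bounded])
  structure(
    list(run_id = run$run_id, Fmax = unname(est["Fmax"]),
         Fb = unname(est["Fb"]), b = unname(est["b"]),
         c = unname(est["c"]), d = unname(est["d"]),
         converged = !at_bound, rss = fit$deviance,
         n_points = length(x)),
    class = "richards_fit")
}

#' @export
print.richards_fit <- function(x, ...) {
  cat(sprintf(
    "<richards_fit '%s'> Fmax=%.4g Fb=%.4g b=%.4g c=%.4g d=%.4g rss=%.3g%s\n",
    x$run_id, x$Fmax, x$Fb, x$b, x$c, x$d, x$rss,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Shape fingerprint of a fitted amplification curve
#'
#' Closed-form inflection-point geometry of the Richards curve:
#' the inflection abscissa is `x_f = c + b*log(d)`, the fluorescence there
#' (above background) is `Yf = Fmax*(1 + 1/d)^(-d)`, the tangent slope is
#' `m = (Fmax/b)*(1 + 1/d)^(-(d+1))`, and the normalized asymmetry is
#' `Asym = (Fmax - 2*Yf)/Fmax = 1 - 2*(1 + 1/d)^(-d)`. For `d = 1` the
#' curve is symmetric: `2*Yf = Fmax`, `Asym = 0`, `m = Fmax/(4b)`. As
#' `d -> Inf`, `Asym -> 1 - 2/e`.
#'
#' @param fit a converged `richards_fit`.
#' @return A `shape_fingerprint`: list with `run_id`, `Fmax`, `Yf`, `m`,
#'   `Asym`, `x_f`.
#' @export
shape_fingerprint <- function(fit) {
  stopifnot(inherits(fit, "richards_fit"))
  if (!isTRUE(fit$converged))
    sod_error("sod_not_converged", sprintf(
      "run '%s': fit did not converge; treat the run as unanalyzable",
      fit$run_id))
  d <- fit$d
  g <- (1 + 1 / d)^(-d)
  Yf <- fit$Fmax * g
  structure(
    list(run_id = fit$run_id, Fmax = fit$Fmax, Yf = Yf,
         m = (fit$Fmax / fit$b) * (1 + 1 / d)^(-(d + 1)),
         Asym = 1 - 2 * g,
         x_f = fit$c + fit$b * log(d)),
    class = "shape_fingerprint")
}

#' Fit every run on a plate
#'
#' Applies [fit_richards()] and [shape_fingerprint()] across a plate and
#' returns one row per run. Runs whose trace never reaches
#' `min_plateau_frac` of the reference plateau (when `ref_plateau` is given)
#' are reported with reason `"no_amplification"` rather than fitted, as are
#' flat traces. Optimizer failures are reported with `converged = FALSE`
#' and reason `"fit_failed"`.
#'
#' @param plate an `amp_plate`.
#' @param ref_plateau reference plateau fluorescence (e.g. median standard
#'   plateau), or `NULL` to skip the plateau screen.
#' @param min_plateau_frac fraction of `ref_plateau` a trace must reach.
#' @param control passed to [fit_richards()].
#' @return data frame: `run_id, role, log10_input, inhibitor,
#'   inhibitor_conc, Fb, Fmax, b, c, d, Yf, m, Asym, x_f, rss, converged,
#'   reason`.
#' @export
fit_plate <- function(plate, ref_plateau = NULL, min_plateau_frac = 0.1,
                      control = list()) {
  stopifnot(inherits(plate, "amp_plate"))
  rows <- lapply(unclass(plate), function(r) {
    base <- data.frame(
      run_id = r$run_id, role = r$role, log10_input = r$log10_input,
      inhibitor = r$inhibitor, inhibitor_conc = r$inhibitor_conc,
      Fb = NA_real_, Fmax = NA_real_, b = NA_real_, c = NA_real_,
      d = NA_real_, Yf = NA_real_, m = NA_real_, Asym = NA_real_,
      x_f = NA_real_, rss = NA_real_, converged = FALSE,
      reason = "", stringsAsFactors = FALSE)
    if (!is.null(ref_plateau) &&
        max(r$fluorescence) - min(r$fluorescence) <
          min_plateau_frac * ref_plateau) {
      base$reason <- "no_amplification"
      return(base)
    }
    fit <- tryCatch(fit_richards(r, control), error = function(e) e)
    if (inherits(fit, "sod_no_amplification")) {
      base$reason <- "no_amplification"
      return(base)
    }
    if (inherits(fit, "error")) {
      base$reason <- "fit_failed"
      return(base)
    }
    base[c("Fb", "Fmax", "b", "c", "d", "rss")] <-
      fit[c("Fb", "Fmax", "b", "c", "d", "rss")]
    base$converged <- fit$converged
    if (fit$converged) {
      fp <- shape_fingerprint(fit)
      base[c("Yf", "m", "Asym", "x_f")] <- fp[c("Yf", "m", "Asym", "x_f")]
      base$reason <- "ok"
    } else {
      base$reason <- "fit_failed"
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
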