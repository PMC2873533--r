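#' Configuration for the synthetic plate simulator
#'
#' Defaults emulate the study conditions of a plasmid dilution-series
#' standard curve: 6 ten-fold dilutions from 3.14e7 down to 3.14e2 copies,
#' 12 replicates each (72 runs), 40 cycles, overall amplification factor
#' 1.9 per cycle. Per-run Richards parameters `(Fmax, b, d)` are drawn
#' lognormally around `shape_means` with coefficients of variation
#' `shape_cvs` (lognormal guarantees positivity); the curve location is
#' `c = c_top + (log10_input_top - log10_input)/log10(efficiency)`, so
#' only curve position -- not shape -- depends on input amount. Gaussian
#' read noise of SD `noise_sd` is added per cycle.
#'
#' Optional inhibition of strength `s` in \[0, 1\] suppresses the plateau
#' (`Fmax * (1 - 0.6 s)`) and the slope (`b * (1 + s)`), and for kind
#' `"plateau_slope_asym"` also increases asymmetry (`d * (1 + 2 s)`);
#' `"plateau_slope_only"` leaves `d` unchanged (quercitin-like kinetics).
#' The coefficients are qualitative dose-response knobs, not chemistry.
#'
#' @param seed integer RNG seed.
#' @param n_concentrations,replicates dilution-series geometry.
#' @param log10_input_top log10 copies of the most concentrated point.
#' @param dilution_step_log10 decades per dilution step.
#' @param efficiency per-cycle amplification factor in (1, 2].
#' @param shape_means named 3-vector, means of `(Fmax, b, d)`.
#' @param shape_cvs named 3-vector, coefficients of variation of the same.
#' @param noise_sd additive Gaussian read noise SD (fluorescence units).
#' @param cycles number of PCR cycles.
#' @param c_top location (cycles) of the most concentrated curve.
#' @param inhibition `NULL`, or `list(kind, strength)` with kind one of
#'   `"plateau_slope_asym"`, `"plateau_slope_only"`.
#' @param inhibitor_name label recorded in the `inhibitor` metadata field
#'   of inhibited runs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_concentrations = 6L,
                       replicates = 12L,
                       log10_input_top = log10(3.14e7),
                       dilution_step_log10 = 1,
                       efficiency = 1.9,
                       shape_means = c(Fmax = 46.41, b = 2.0, d = 1.2),
                       shape_cvs = c(Fmax = 0.13, b = 0.10, d = 0.08),
                       noise_sd = 0.05,
                       cycles = 40L,
                       c_top = 14,
                       inhibition = NULL,
                       inhibitor_name = "synthetic_inhibitor") {
  stopifnot(replicates >= 1L, n_concentrations >= 1L,
            efficiency > 1, efficiency <= 2,
            noise_sd >= 0, cycles >= 10L,
            length(shape_means) == 3L, length(shape_cvs) == 3L,
            all(shape_means > 0), all(shape_cvs >= 0))
  if (!is.null(inhibition)) {
    inhibition$kind <- match.arg(inhibition$kind,
                                 c("plateau_slope_asym",
                                   "plateau_slope_only"))
    stopifnot(is_scalar_number(inhibition$strength),
              inhibition$strength >= 0, inhibition$strength <= 1)
  }
  names(shape_means) <- names(shape_cvs) <- c("Fmax", "b", "d")
  structure(list(
    seed = as.integer(seed), n_concentrations = as.integer(n_concentrations),
    replicates = as.integer(replicates), log10_input_top = log10_input_top,
    dilution_step_log10 = dilution_step_log10, efficiency = efficiency,
    shape_means = shape_means, shape_cvs = shape_cvs, noise_sd = noise_sd,
    cycles = as.integer(cycles), c_top = c_top, inhibition = inhibition,
    inhibitor_name = inhibitor_name), class = "sim_config")
}

# lognormal draw with arithmetic mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a plate of amplification runs
#'
#' Draws per-run Richards shape parameters, evaluates the model at each
#' cycle and adds read noise, per [sim_config()]. Without inhibition the
#' runs are dilution-series standards (`role = "standard"`); with an
#' `inhibition` entry they are inhibited test runs (`role = "test"`,
#' annotated with the inhibitor name and strength). Fully reproducible
#' from the config seed. Inhibition of strength 0 yields bit-identical
#' traces to the uninhibited branch under the same seed.
#'
#' @param config a [sim_config()].
#' @param id_prefix prefix for generated run ids.
#' @return list with `runs` (an `amp_plate`) and `truth` (data frame of
#'   generating parameters per run: `run_id, log10_input, Fmax_true,
#'   b_true, c_true, d_true, inhibition_kind, inhibition_strength`).
#' @export
simulate_plate <- function(config = sim_config(), id_prefix = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  inhibited <- !is.null(config$inhibition)
  s <- if (inhibited) config$inhibition$strength else 0
  kind <- if (inhibited) config$inhibition$kind else NA_character_
  if (is.null(id_prefix)) id_prefix <- if (inhibited) "I" else "S"
  x <- seq_len(config$cycles)

  runs <- list(); truth <- list(); k <- 0L
  for (ci in seq_len(config$n_concentrations)) {
    log10_n <- config$log10_input_top -
      (ci - 1L) * config$dilution_step_log10
    c_loc <- config$c_top +
      (config$log10_input_top - log10_n) / log10(config$efficiency)
    for (ri in seq_len(config$replicates)) {
      k <- k + 1L
      Fmax <- rlnorm_mean_cv(1, config$shape_means["Fmax"],
                             config$shape_cvs["Fmax"])
      b <- rlnorm_mean_cv(1, config$shape_means["b"], config$shape_cvs["b"])
      d <- rlnorm_mean_cv(1, config$shape_means["d"], config$shape_cvs["d"])
      # inhibition applied after the draws so strength 0 reproduces the
      # uninhibited RNG stream exactly
      Fmax_i <- Fmax * (1 - 0.6 * s)
      b_i <- b * (1 + 1.0 * s)
      d_i <- if (inhibited && kind == "plateau_slope_asym")
        d * (1 + 2.0 * s) else d
      f <- richards_model(x, Fmax_i, b_i, c_loc, d_i) +
        rnorm(config$cycles, sd = config$noise_sd)
      id <- sprintf("%s%d_%02d", id_prefix, ci, ri)
      runs[[k]] <- amp_run(
        id, x, f, role = if (inhibited) "test" else "standard",
        log10_input = log10_n,
        inhibitor = if (inhibited) config$inhibitor_name else NA_character_,
        inhibitor_conc = if (inhibited) s else NA_real_)
      truth[[k]] <- data.frame(
        run_id = id, log10_input = log10_n, Fmax_true = Fmax_i,
        b_true = b_i, c_true = c_loc, d_true = d_i,
        inhibition_kind = kind, inhibition_strength = s,
        stringsAsFactors = FALSE)
    }
  }
  list(runs = new_plate(runs), truth = do.call(rbind, truth))
}

#' Simulate a full inhibition study
#'
#' A dilution-series standard plate plus graded inhibited test runs at a
#' fixed spiked input (default 3.5e4 copies), mirroring an inhibitor
#' titration experiment: one batch of `inhibited_replicates` runs per
#' strength in `strengths`. Each batch uses a seed derived from `seed` so
#' the whole study is reproducible from one integer.
#'
#' @param seed integer master seed.
#' @param strengths inhibition strengths in \[0, 1\], one batch each.
#' @param kind inhibition kind (see [sim_config()]).
#' @param inhibited_replicates runs per strength.
#' @param inhibited_log10_input log10 spiked copies of the test runs.
#' @param ... further arguments passed to [sim_config()] (shared by the
#'   standard and inhibited branches).
#' @return list with `runs` (combined `amp_plate`) and `truth`.
#' @export
simulate_study <- function(seed = 1L,
                           strengths = c(0.2, 0.4, 0.6, 0.8, 1.0),
                           kind = "plateau_slope_asym",
                           inhibited_replicates = 6L,
                           inhibited_log10_input = log10(3.5e4),
                           ...) {
  base <- simulate_plate(sim_config(seed = seed, ...))
  runs <- base$runs
  truth <- base$truth
  for (i in seq_along(strengths)) {
    cfg <- sim_config(
      seed = seed + 10000L * i, n_concentrations = 1L,
      replicates = inhibited_replicates,
      log10_input_top = inhibited_log10_input,
      inhibition = list(kind = kind, strength = strengths[i]), ...)
    # keep c at the position this input would have on the standard plate
    cfg$c_top <- base_config_c(seed, inhibited_log10_input, ...)
    batch <- simulate_plate(cfg, id_prefix = sprintf("I%d_", i))
    runs <- c(runs, batch$runs)
    truth <- rbind(truth, batch$truth)
  }
  list(runs = runs, truth = truth)
}

# location a given input amount would have on the uninhibited standard plate
base_config_c <- function(seed, log10_input, ...) {
  cfg <- sim_config(seed = seed, ...)
  cfg$c_top + (cfg$log10_input_top - log10_input) / log10(cfg$efficiency)
}
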