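test_that("richards_model evaluates the five-parameter sigmoid", {
  # logistic midpoint: at x = c with d = 1 the curve sits at Fb + Fmax/2
  expect_equal(richards_model(20, Fmax = 40, b = 2, c = 20, d = 1, Fb = 3),
               23)
  # direct evaluation with d = 2: 2 + 40 * 2^-2
  expect_equal(richards_model(20, Fmax = 40, b = 2, c = 20, d = 2, Fb = 2),
               12)
  # monotone rise from Fb to Fb + Fmax, no overflow at extreme arguments
  x <- seq(-5000, 5000, length.out = 2001)
  f <- richards_model(x, Fmax = 40, b = 2, c = 20, d = 3, Fb = 1)
  expect_true(all(diff(f) >= 0))
  expect_equal(f[1], 1)
  expect_equal(f[length(f)], 41)
})

test_that("fit_richards recovers generating parameters from noiseless traces", {
  for (d_true in c(1, 2)) {
    run <- make_richards_run(Fmax = 40, b = 2, c = 20, d = d_true, Fb = 2)
    fit <- fit_richards(run)
    expect_true(fit$converged)
    est <- unlist(fit[c("Fmax", "b", "c", "d", "Fb")])
    truth <- c(Fmax = 40, b = 2, c = 20, d = d_true, Fb = 2)
    expect_lt(max(abs(est - truth) / abs(truth)), 1e-4)
  }
})

test_that("fit_richards handles degenerate inputs as specified", {
  flat <- amp_run("flat", 1:40, rep(1, 40) + 1e-9 * (1:40))
  expect_error(fit_richards(flat), class = "sod_no_amplification")
  short <- amp_run("short", 1:5, c(0, 0.1, 0.5, 2, 4))
  expect_error(fit_richards(short), class = "sod_too_few_points")
})

test_that("shape_fingerprint matches the closed forms and symmetry identities", {
  mk <- function(Fmax, b, d) structure(
    list(run_id = "t", Fmax = Fmax, Fb = 0, b = b, c = 20, d = d,
         converged = TRUE, rss = 0, n_points = 40),
    class = "richards_fit")

  fp <- shape_fingerprint(mk(40, 2, 1))       # symmetric logistic
  expect_equal(fp$Yf, 20)
  expect_equal(fp$m, 5)                       # Fmax/(4b)
  expect_equal(fp$Asym, 0, tolerance = 1e-9)

  fp <- shape_fingerprint(mk(40, 2, 2))
  expect_equal(fp$Yf, 40 * 1.5^-2, tolerance = 1e-9)
  expect_equal(fp$m, 20 * 1.5^-3, tolerance = 1e-9)
  expect_equal(fp$Asym, 1 / 9, tolerance = 1e-6)

  # Gompertz limit: Asym -> 1 - 2/e as d grows without bound
  fp <- shape_fingerprint(mk(40, 2, 1e6))
  expect_equal(fp$Asym, 1 - 2 / exp(1), tolerance = 1e-5)

  # Asym identity holds exactly for every fingerprint
  for (d in c(0.3, 1, 1.7, 6)) {
    fp <- shape_fingerprint(mk(37, 1.4, d))
    expect_equal(fp$Asym, (fp$Fmax - 2 * fp$Yf) / fp$Fmax, tolerance = 1e-12)
    expect_true(fp$Yf > 0 && fp$Yf < fp$Fmax)
  }

  expect_error(
    shape_fingerprint(structure(list(run_id = "x", converged = FALSE),
                                class = "richards_fit")),
    class = "sod_not_converged")
})

test_that("closed-form inflection geometry agrees with the numerical oracle", {
  set.seed(101)
  for (i in 1:25) {
    Fmax <- runif(1, 10, 80); b <- runif(1, 0.8, 4)
    c0 <- runif(1, 12, 28); d <- runif(1, 0.3, 6)
    fit <- structure(
      list(run_id = "o", Fmax = Fmax, Fb = 0, b = b, c = c0, d = d,
           converged = TRUE, rss = 0, n_points = 40),
      class = "richards_fit")
    fp <- shape_fingerprint(fit)
    or <- numeric_inflection(Fmax, b, c0, d)
    expect_equal(fp$x_f, or$x_f, tolerance = 1e-5)
    expect_equal(fp$Yf, or$Yf, tolerance = 1e-5)
    expect_equal(fp$m, or$m, tolerance = 1e-5)
  }
})

test_that("fingerprint obeys shift and scale equivariance", {
  set.seed(11)
  run <- make_richards_run(Fmax = 50, b = 1.8, c = 22, d = 1.4, Fb = 1)
  run$fluorescence <- run$fluorescence + rnorm(40, sd = 0.02)
  f0 <- fit_richards(run)
  fp0 <- shape_fingerprint(f0)

  # shifting the cycle axis by 5 shifts c only
  shifted <- amp_run(run$run_id, run$cycles + 5L, run$fluorescence)
  f1 <- fit_richards(shifted)
  fp1 <- shape_fingerprint(f1)
  expect_equal(f1$c, f0$c + 5, tolerance = 1e-4)
  expect_equal(fp1$Yf, fp0$Yf, tolerance = 1e-5)
  expect_equal(fp1$m, fp0$m, tolerance = 1e-5)
  expect_equal(fp1$Asym, fp0$Asym, tolerance = 1e-5)

  # scaling fluorescence by k scales Fmax, Yf, m, Fb; d and Asym invariant
  k <- 3.7
  scaled <- amp_run(run$run_id, run$cycles, k * run$fluorescence)
  f2 <- fit_richards(scaled)
  fp2 <- shape_fingerprint(f2)
  expect_equal(fp2$Fmax, k * fp0$Fmax, tolerance = 1e-4)
  expect_equal(fp2$Yf, k * fp0$Yf, tolerance = 1e-4)
  expect_equal(fp2$m, k * fp0$m, tolerance = 1e-4)
  expect_equal(f2$Fb, k * f0$Fb, tolerance = 1e-3)
  expect_equal(f2$d, f0$d, tolerance = 1e-4)
  expect_equal(fp2$Asym, fp0$Asym, tolerance = 1e-5)
})

test_that("refitting a fit's own noiseless prediction is idempotent", {
  run <- make_richards_run(Fmax = 44, b = 2.3, c = 18, d = 1.8, Fb = 0.5)
  fit <- fit_richards(run)
  pred <- amp_run("pred", run$cycles,
                  richards_model(as.numeric(run$cycles), fit$Fmax, fit$b,
                                 fit$c, fit$d, fit$Fb))
  refit <- fit_richards(pred)
  for (p in c("Fmax", "b", "c", "d", "Fb"))
    expect_equal(refit[[p]], fit[[p]], tolerance = 1e-6)
})

test_that("fit_plate screens unamplified traces against the reference plateau", {
  good <- make_richards_run("g", Fmax = 40, b = 2, c = 20, d = 1)
  weak <- amp_run("w", 1:40, richards_model(1:40, 2, 2, 35, 1))
  plate <- structure(list(g = good, w = weak), class = "amp_plate")
  fits <- fit_plate(plate, ref_plateau = 40, min_plateau_frac = 0.1)
  expect_equal(fits$reason, c("ok", "no_amplification"))
  expect_equal(fits$converged, c(TRUE, FALSE))
})
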