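# Shared fixtures and independent oracles, built in code.

# Noiseless amplification run from known Richards parameters.
make_richards_run <- function(id = "r", Fmax = 40, b = 2, c = 20, d = 1,
                              Fb = 0, cycles = 40, role = "test",
                              log10_input = NA_real_) {
  x <- seq_len(cycles)
  amp_run(id, x, richards_model(x, Fmax, b, c, d, Fb),
          role = role, log10_input = log10_input)
}

# Brute-force inflection oracle: locate the maximum of the numerical first
# derivative on a fine grid (coarse pass, then refinement at step `h`),
# independent of the closed forms under test.
numeric_inflection <- function(Fmax, b, c, d, Fb = 0, h = 1e-4) {
  fun <- function(x) richards_model(x, Fmax, b, c, d, Fb)
  span <- seq(c - 12 * b, c + 12 * b, by = 0.01)
  d1 <- (fun(span + 0.01) - fun(span - 0.01)) / 0.02
  x0 <- span[which.max(d1)]
  fine <- seq(x0 - 0.02, x0 + 0.02, by = h)
  d1f <- (fun(fine + h) - fun(fine - h)) / (2 * h)
  i <- which.max(d1f)
  # parabolic vertex through the three top derivative samples refines the
  # argmax below grid resolution (the derivative is locally quadratic)
  num <- d1f[i - 1] - d1f[i + 1]
  den <- 2 * (d1f[i - 1] - 2 * d1f[i] + d1f[i + 1])
  xf <- fine[i] + h * num / den
  list(x_f = xf,
       Yf = fun(xf) - Fb,
       m = (fun(xf + h) - fun(xf - h)) / (2 * h))
}

# Explicit 3x3 matrix inverse by cofactor expansion: the independent oracle
# for the Mahalanobis quadratic form.
cofactor_inverse_3x3 <- function(A) {
  stopifnot(all(dim(A) == c(3, 3)))
  cof <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    M <- A[-i, -j, drop = FALSE]
    cof[i, j] <- (-1)^(i + j) * (M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  }
  t(cof) / det(A)
}

# Random symmetric positive-definite 3x3 matrix.
random_spd_3x3 <- function() {
  A <- matrix(rnorm(9), 3, 3)
  crossprod(A) + diag(3) * 0.1
}

# Trivariate-normal fingerprint generator on the Table-1 scale, used for
# calibration and recovery checks.
fingerprint_generator <- function() {
  mu <- c(Fmax = 46.41, Yf = 23.89, m = 8.61)
  sdv <- c(6.07, 2.86, 1.20)
  corr <- matrix(c(1, 0.7, 0.3,
                   0.7, 1, 0.5,
                   0.3, 0.5, 1), 3, 3)
  sigma <- diag(sdv) %*% corr %*% diag(sdv)
  dimnames(sigma) <- list(names(mu), names(mu))
  list(mu = mu, sigma = sigma,
       draw = function(n) {
         y <- sweep(matrix(rnorm(n * 3), n, 3) %*% chol(sigma), 2, mu, "+")
         colnames(y) <- names(mu)
         as.data.frame(y)
       })
}
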