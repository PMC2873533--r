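test_that("build_reference estimates mean and covariance, guarding degeneracy", {
  gen <- fingerprint_generator()
  set.seed(3)
  y <- gen$draw(72)
  expect_warning(ref <- build_reference(y[1:12, ]), "asymptotic")
  ref <- build_reference(y)
  expect_equal(ref$n_ref, 72L)
  expect_equal(unname(ref$mu), unname(colMeans(as.matrix(y))),
               tolerance = 1e-12)
  expect_equal(ref$sigma, cov(as.matrix(y)), tolerance = 1e-12)
  # mu within 3 SE per coordinate of the generating mean
  se <- sqrt(diag(gen$sigma) / 72)
  expect_true(all(abs(ref$mu - gen$mu) < 3 * se))

  same <- y[rep(1, 12), ]
  expect_error(suppressWarnings(build_reference(same)),
               class = "sod_singular_reference")
  expect_error(build_reference(y[1:5, ]),
               class = "sod_degenerate_reference")
})

test_that("sod_test computes the Mahalanobis chi-squared call", {
  gen <- fingerprint_generator()
  set.seed(4)
  ref <- build_reference(gen$draw(72))

  at_mu <- as.data.frame(as.list(setNames(ref$mu, c("Fmax", "Yf", "m"))))
  r <- sod_test(at_mu, ref)
  expect_equal(r$d2, 0, tolerance = 1e-12)
  expect_false(r$is_outlier)

  # identity covariance reduces to squared Euclidean distance
  id_ref <- structure(list(mu = c(Fmax = 0, Yf = 0, m = 0), sigma = diag(3),
                           n_ref = 72L,
                           parameter_order = c("Fmax", "Yf", "m")),
                      class = "sod_reference")
  r2 <- sod_test(data.frame(Fmax = 1, Yf = 2, m = 2), id_ref)
  expect_equal(r2$d2, 9, tolerance = 1e-12)
  expect_true(r2$is_outlier)  # 9 > 7.81

  expect_error(sod_test(data.frame(Fmax = NA_real_, Yf = 1, m = 1), ref),
               class = "sod_bad_fingerprint")
})

test_that("Mahalanobis distances match the explicit cofactor-inverse oracle", {
  set.seed(6)
  for (i in 1:20) {
    sigma <- random_spd_3x3()
    mu <- rnorm(3)
    y <- matrix(rnorm(15), 5, 3)
    colnames(y) <- c("Fmax", "Yf", "m")
    ref <- structure(list(mu = setNames(mu, colnames(y)), sigma = sigma,
                          n_ref = 72L, parameter_order = colnames(y)),
                     class = "sod_reference")
    d2 <- sod_test(as.data.frame(y), ref)$d2
    inv <- cofactor_inverse_3x3(sigma)
    d2_oracle <- apply(y, 1, function(v)
      drop(t(v - mu) %*% inv %*% (v - mu)))
    expect_equal(d2, unname(d2_oracle), tolerance = 1e-10)
    # and the library routine agrees too
    expect_equal(d2, unname(stats::mahalanobis(y, mu, sigma)),
                 tolerance = 1e-10)
  }
})

test_that("d2 is invariant under invertible affine maps of all fingerprints", {
  gen <- fingerprint_generator()
  set.seed(9)
  y <- as.matrix(gen$draw(72))
  te <- as.matrix(gen$draw(10))
  ref <- build_reference(y)
  d2_0 <- sod_test(te, ref)$d2
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    off <- rnorm(3)
    yt <- sweep(y %*% t(A), 2, off, "+")
    tet <- sweep(te %*% t(A), 2, off, "+")
    colnames(yt) <- colnames(tet) <- c("Fmax", "Yf", "m")
    d2_t <- sod_test(tet, build_reference(yt))$d2
    expect_equal(d2_t, d2_0, tolerance = 1e-8)
  }
})

test_that("reference distances sum to 3(n-1) and look chi-squared under normality", {
  gen <- fingerprint_generator()
  set.seed(10)
  y <- gen$draw(72)
  ref <- build_reference(y)
  diag_ <- multivariate_normality_d2(y, ref)
  # algebraic identity for the n-1 covariance denominator
  expect_equal(sum(diag_$table$d2), 3 * (72 - 1), tolerance = 1e-8)
  expect_true(all(diff(diag_$table$d2) >= 0))

  big <- gen$draw(500)
  qq <- multivariate_normality_d2(big, build_reference(big))
  expect_gt(qq$qq_cor, 0.99)

  expect_error(build_reference(gen$draw(2)),
               class = "sod_degenerate_reference")
})

test_that("SOD flags about 5% of null fingerprints", {
  gen <- fingerprint_generator()
  set.seed(20)
  rates <- replicate(10, {
    ref <- build_reference(gen$draw(72))
    mean(sod_test(gen$draw(2000), ref)$is_outlier)
  })
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.08)
})

test_that("K-S normality check uses the sqrt(n)*D convention", {
  set.seed(15)
  x <- rnorm(72, 1.88, 0.02)
  ks <- ks_normality(x)
  expect_equal(ks$ks_z, sqrt(72) * ks$D, tolerance = 1e-12)
  expect_gt(ks$p, 0.01)   # null draws rarely rejected
  # far-apart bimodal mixture is decisively non-normal
  bim <- c(rnorm(50, 0, 0.2), rnorm(50, 10, 0.2))
  expect_lt(ks_normality(bim)$p, 0.01)
  expect_error(ks_normality(rep(1, 20)),
               class = "sod_degenerate_reference")
  expect_error(ks_normality(rnorm(5)), class = "sod_too_few_points")
})

test_that("correlation t-test matches the analytic p and the library routine", {
  # exactly orthogonal vectors: r = 0, t = 0, p = 1
  v <- c(-1, 0, 1, -1, 0, 1)
  g <- c(1, 1, 1, -1, -1, -1)
  ct0 <- correlation_t_test(v, g)
  expect_equal(ct0$r, 0, tolerance = 1e-12)
  expect_equal(ct0$p, 1, tolerance = 1e-12)

  # R2 = 0.017 at n = 72: the published weak-correlation scale, p near 0.28
  # (R2 is only quoted to 3 decimals, so p carries ~0.01 of rounding slack)
  r_target <- sqrt(0.017)
  t_expect <- r_target * sqrt(70) / sqrt(1 - 0.017)
  p_expect <- 2 * pt(-t_expect, 70)
  expect_lt(abs(p_expect - 0.28), 0.01)

  set.seed(16)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  ct1 <- correlation_t_test(a, b)
  lib <- cor.test(a, b)
  expect_equal(ct1$t, unname(lib$statistic), tolerance = 1e-10)
  expect_equal(ct1$p, lib$p.value, tolerance = 1e-10)

  # perfect correlation: t diverges, p collapses to 0
  ct2 <- correlation_t_test(1:20 + 1e-12 * rnorm(20), 1:20)
  expect_lt(ct2$p, 1e-10)
  expect_error(correlation_t_test(rep(1, 10), rnorm(10)),
               class = "sod_degenerate_reference")
})
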