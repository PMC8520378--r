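# Sparse solvers: OMP, ISTA/FISTA, the exhaustive l0 oracle, and metrics.

test_that("OMP recovers a 1-sparse signal exactly with identity sensing", {
  for (name in cs_bases()) {
    basis <- build_basis(name, 16)
    s <- numeric(16); s[5] <- 2
    x <- synthesize(basis, s)
    x <- if (is.complex(x)) Re(x) else x
    phi <- diag(16)
    res <- omp(measure(phi, x), phi, basis, K = 1)
    expect_lt(res$residual_l2, 1e-9)
    expect_lt(rel_err(res$x_hat, x), 1e-9)
  }
})

test_that("OMP achieves exact recovery on the canonical K=5 instance", {
  inst <- make_ksparse_instance(N = 300, M = 100, K = 5, seed = 7)
  res <- omp(inst$y, inst$phi, inst$basis, K = 5)
  expect_lt(rel_err(res$x_hat, inst$x), 1e-6)
  expect_setequal(res$support, inst$support)
  m <- evaluate_recovery(inst$x, res, inst$support)
  expect_equal(m$support_precision, 1)
  expect_equal(m$support_recall, 1)
})

test_that("OMP tracks the exhaustive l0 oracle on small planted instances", {
  # Greedy selection is not guaranteed to find the global l0 optimum (that
  # is why the l0 problem is hard), but on random 2-sparse instances it
  # should agree with the oracle almost always, and can never beat it.
  agree <- 0L
  for (seed in 1:20) {
    inst <- make_ksparse_instance(N = 10, M = 6, K = 2, seed = seed + 300)
    o <- exhaustive_l0(inst$y, inst$phi, inst$basis, K = 2)
    g <- omp(inst$y, inst$phi, inst$basis, K = 2)
    expect_lte(o$residual_l2, g$residual_l2 + 1e-10)
    # the planted 2-sparse truth is the oracle's optimum
    expect_lt(o$residual_l2, 1e-8)
    if (setequal(o$support, g$support)) {
      agree <- agree + 1L
      expect_lt(rel_err(g$x_hat, inst$x), 1e-6)
    }
  }
  expect_gte(agree, 16L)
})

test_that("the exhaustive oracle is exact, guarded, and independently verifiable", {
  inst <- make_ksparse_instance(N = 8, M = 5, K = 2, seed = 11)
  o <- exhaustive_l0(inst$y, inst$phi, inst$basis, K = 2)
  # second, independent enumeration via lm.fit over all supports
  A <- unclass(inst$phi) %*% basis_matrix(inst$basis)
  best <- l2(inst$y)
  for (k in 1:2) {
    cmb <- utils::combn(8, k)
    for (i in seq_len(ncol(cmb))) {
      fit <- stats::lm.fit(A[, cmb[, i], drop = FALSE], as.numeric(inst$y))
      best <- min(best, l2(fit$residuals))
    }
  }
  expect_equal(o$residual_l2, best, tolerance = 1e-9)
  # K = 0 returns the zero solution
  o0 <- exhaustive_l0(inst$y, inst$phi, inst$basis, K = 0)
  expect_equal(o0$residual_l2, l2(inst$y))
  expect_length(o0$support, 0)
  expect_error(exhaustive_l0(inst$y, inst$phi, build_basis("dct", 8), K = 4),
               class = "cspa_instance_too_large")
  big <- make_ksparse_instance(N = 32, M = 16, K = 2, seed = 1)
  expect_error(exhaustive_l0(big$y, big$phi, big$basis, K = 2),
               class = "cspa_instance_too_large")
})

test_that("ISTA reduces to element-wise soft thresholding when A is the identity", {
  y <- c(2, -0.5, 0.05, -3, 1)
  lam <- 0.6
  res <- ista_l1(y, diag(5), diag(5), lam = lam, max_iter = 2000, tol = 1e-14)
  expect_equal(res$x_hat, sign(y) * pmax(abs(y) - lam, 0), tolerance = 1e-8)
})

test_that("a large enough penalty zeroes the l1 solution", {
  inst <- make_ksparse_instance(N = 32, M = 16, K = 3, seed = 5)
  A <- unclass(inst$phi) %*% basis_matrix(inst$basis)
  lam_max <- max(abs(crossprod(A, as.numeric(inst$y))))
  res <- ista_l1(inst$y, inst$phi, inst$basis, lam = lam_max * 1.01)
  expect_equal(max(abs(res$s_hat)), 0)
  expect_error(ista_l1(inst$y, inst$phi, inst$basis, lam = 0),
               class = "cspa_invalid_penalty")
})

test_that("ISTA and monotone FISTA objective traces never increase", {
  for (seed in 1:5) {
    inst <- make_ksparse_instance(N = 64, M = 32, K = 4, seed = seed + 50)
    for (acc in c(FALSE, TRUE)) {
      res <- ista_l1(inst$y, inst$phi, inst$basis, lam = 0.05,
                     max_iter = 300, accelerated = acc)
      expect_true(all(diff(res$objective_trace) <= 1e-12))
    }
  }
})

test_that("FISTA with debiasing recovers the canonical K=5 instance", {
  inst <- make_ksparse_instance(N = 300, M = 100, K = 5, seed = 7)
  res <- fista_l1(inst$y, inst$phi, inst$basis, lam = 1e-2,
                  max_iter = 3000, debias = TRUE)
  expect_lt(rel_err(res$x_hat, inst$x), 1e-3)
})

test_that("a photoacoustic A-line is recovered via its time-domain sparsity", {
  # N-wave pulse trains are sparse in time, not in frequency: the identity
  # dictionary is the appropriate sparse model for this signal class.
  cfg <- pa_phantom_config(noise_sigma = 0)
  x <- as.numeric(generate_pa_aline(cfg))
  K <- sum(x != 0)                     # ~13 samples per absorber
  expect_lt(K, 50)
  phi <- make_measurement_matrix(180, length(x), "gaussian", seed = 31)
  y <- measure(phi, x)
  res <- omp(y, phi, diag(length(x)), K = K)
  expect_lt(rel_err(res$x_hat, x), 1e-6)
})

test_that("recovery degrades continuously with measurement noise", {
  inst <- make_ksparse_instance(N = 128, M = 64, K = 4, seed = 21)
  scale <- l2(inst$y) / sqrt(64)
  errs <- sapply(c(0, 1e-4, 1e-3, 1e-2) * scale, function(sig) {
    y <- measure(inst$phi, inst$x, noise_sigma = sig, seed = 99)
    rel_err(omp(y, inst$phi, inst$basis, K = 4)$x_hat, inst$x)
  })
  expect_true(all(errs < 0.05))           # no catastrophic failure
  expect_lt(errs[1], 1e-9)                # exact at zero noise
})

test_that("infeasible OMP sparsity levels are rejected", {
  inst <- make_ksparse_instance(N = 16, M = 4, K = 2, seed = 2)
  expect_error(omp(inst$y, inst$phi, inst$basis, K = 5),
               class = "cspa_infeasible_k")
})

test_that("recovery metrics match hand-computed values", {
  x <- c(1, 2, 3, 4)
  # perfect recovery
  m <- evaluate_recovery(x, x, support_true = c(1, 2))
  expect_equal(m$relative_l2_error, 0)
  expect_equal(m$psnr_db, Inf)
  # one-sample miss: mse = 0.25, peak = 4 -> PSNR = 10 log10(64) = 18.0618 dB
  m <- evaluate_recovery(x, c(1, 2, 3, 5))
  expect_equal(m$psnr_db, 10 * log10(64), tolerance = 1e-12)
  expect_equal(m$relative_l2_error, 1 / l2(x), tolerance = 1e-12)
  # zero estimate vs nonzero truth
  inst <- make_ksparse_instance(N = 16, M = 8, K = 2, seed = 3)
  z <- exhaustive_l0(inst$y, inst$phi, inst$basis, K = 0)
  m <- evaluate_recovery(inst$x, z, inst$support)
  expect_equal(m$relative_l2_error, 1)
  expect_equal(m$support_recall, 0)
  # zero truth: absolute error reported with a flag
  m <- evaluate_recovery(numeric(4), c(0, 0.3, 0.4, 0))
  expect_true(m$absolute_error)
  expect_equal(m$relative_l2_error, 0.5)
})

test_that("solvers handle the complex Fourier basis via realification", {
  N <- 32
  basis <- build_basis("fft", N)
  # real 1-frequency signal: 2-sparse in the DFT (conjugate pair)
  n <- 0:(N - 1)
  x <- cos(2 * pi * 3 * n / N)
  phi <- make_measurement_matrix(16, N, "gaussian", seed = 13)
  y <- measure(phi, x)
  res <- omp(y, phi, basis, K = 4)
  expect_lt(rel_err(res$x_hat, x), 1e-6)
})
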