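# Random measurement operators and their incoherence with sparse bases.
#
# A measurement matrix Phi (M x N, M <= N) maps a length-N signal to M linear
# observations y = Phi x (+ optional i.i.d. Gaussian noise).  Rows are
# normalized to unit l2 norm so that coherence values and noise levels are
# comparable across ensembles.  Recovery from few measurements requires Phi
# to be incoherent with the sparse basis Psi: mutual coherence
# mu = sqrt(N) * max |<phi_k, psi_j>| lies in [1, sqrt(N)], with mu = 1 the
# maximally incoherent (spike-Fourier) case.

#' Build a random measurement matrix
#'
#' @param M Number of measurements (rows), `1 <= M <= N`.
#' @param N Signal length (columns).
#' @param ensemble `"gaussian"` (i.i.d. normal entries, rows normalized),
#'   `"bernoulli"` (random signs, rows normalized to unit norm), or
#'   `"subsample"` (`M` distinct rows of the identity chosen uniformly).
#' @param seed Integer seed; the matrix is reproducible per
#'   `(ensemble, M, N, seed)`.
#' @return An `M x N` numeric matrix of class `measurement_matrix` with unit
#'   l2-norm rows and attributes `ensemble` and `seed`.
#' @export
make_measurement_matrix <- function(M, N,
                                    ensemble = c("gaussian", "bernoulli",
                                                 "subsample"),
                                    seed = 1L) {
  N <- check_count(N, "N")
  M <- check_count(M, "M")
  if (M > N) {
    cspa_stop(sprintf("M = %d exceeds N = %d: a measurement matrix is wide",
                      M, N), "cspa_invalid_shape")
  }
  ensemble <- match.arg(ensemble)
  phi <- with_seed(seed, switch(
    ensemble,
    gaussian = matrix(stats::rnorm(M * N), M, N),
    bernoulli = matrix(sample(c(-1, 1), M * N, replace = TRUE), M, N),
    subsample = {
      rows <- sample.int(N, M)
      diag(N)[rows, , drop = FALSE]
    }))
  if (ensemble != "subsample") {
    phi <- phi / sqrt(rowSums(phi^2))
  }
  structure(phi, ensemble = ensemble, seed = seed,
            class = c("measurement_matrix", class(phi)))
}

#' @export
print.measurement_matrix <- function(x, ...) {
  cat(sprintf("<measurement_matrix> %d x %d, ensemble = %s, seed = %s\n",
              nrow(x), ncol(x), attr(x, "ensemble"),
              format(attr(x, "seed"))))
  invisible(x)
}

check_phi <- function(phi, N = NULL) {
  if (!is.matrix(phi) || !is.numeric(phi)) {
    cspa_stop("`phi` must be a numeric matrix", "cspa_invalid_shape")
  }
  if (!is.null(N) && ncol(phi) != N) {
    cspa_stop(sprintf("measurement matrix has %d columns but the signal/basis has length %d",
                      ncol(phi), N), "cspa_dimension_error")
  }
  phi
}

#' Acquire compressed measurements of a signal
#'
#' Computes `y = Phi x + eps` with `eps ~ N(0, noise_sigma^2)` i.i.d.,
#' drawn under `seed` (so the noise is reproducible independently of the
#' matrix seed).  With `noise_sigma = 0` the product is exact and `seed`
#' is not consulted.
#'
#' @param phi Measurement matrix (`measurement_matrix` or plain numeric
#'   matrix with `ncol(phi) == length(x)`).
#' @param x Real signal.
#' @param noise_sigma Noise standard deviation, `>= 0`.
#' @param seed Integer seed for the noise draw.
#' @return Numeric measurement vector of length `nrow(phi)` with attribute
#'   `noise_sigma`.
#' @export
measure <- function(phi, x, noise_sigma = 0, seed = 1L) {
  check_signal(x)
  check_phi(phi, length(x))
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma < 0) {
    cspa_stop("`noise_sigma` must be a single non-negative number",
              "cspa_invalid_noise")
  }
  y <- drop(unclass(phi) %*% x)
  if (noise_sigma > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sigma))
  }
  structure(y, noise_sigma = noise_sigma)
}

#' Mutual coherence between a measurement matrix and a sparse basis
#'
#' `sqrt(N)` times the largest absolute inner product between unit-normalized
#' rows of `phi` and columns of `Psi`.  Always in `[1, sqrt(N)]`: identity
#' rows against the unitary Fourier basis attain the lower bound 1, identity
#' rows against the identity attain `sqrt(N)`.
#'
#' @param phi Measurement matrix.
#' @param basis A `cs_basis`, or a plain (numeric or complex) `N x N` matrix
#'   whose columns form the dictionary.
#' @return Coherence value in `[1, sqrt(N)]`.
#' @export
mutual_coherence <- function(phi, basis) {
  Psi <- if (inherits(basis, "cs_basis")) basis_matrix(basis) else basis
  if (!is.matrix(Psi)) {
    cspa_stop("`basis` must be a cs_basis or a matrix", "cspa_unsupported_basis")
  }
  check_phi(phi, nrow(Psi))
  N <- ncol(phi)
  phin <- unclass(phi) / sqrt(rowSums(unclass(phi)^2))
  Psin <- sweep(Psi, 2, sqrt(colSums(Mod(Psi)^2)), "/")
  sqrt(N) * max(Mod(phin %*% Psin))
}
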