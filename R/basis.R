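# Orthonormal sparse bases for 1-D signals.
#
# Each basis is an orthonormal N x N operator Psi; a signal x relates to its
# coefficient vector s by x = Psi s (synthesis) and s = Psi^H x (analysis).
# All built-ins are exactly orthonormal, so the round trip is the identity and
# Parseval holds (||s||_2 = ||x||_2).  Fast O(N log N) paths through the FFT
# are used wherever the kernel admits one; the explicit matrix is available
# for inspection and cross-checks via basis_matrix().

CS_BASES <- c("fft", "dct", "dst", "dht", "wtransform")

#' Names of the built-in sparse bases
#'
#' @return Character vector: `"fft"` (unitary discrete Fourier), `"dct"`
#'   (orthonormal DCT-II), `"dst"` (orthonormal DST-I), `"dht"` (orthonormal
#'   discrete Hartley) and `"wtransform"` (Wang discrete W family).
#' @export
cs_bases <- function() CS_BASES

#' Construct an orthonormal sparse basis
#'
#' Builds one of the five transform bases used for sparse decomposition of
#' A-line signals.  The object is lightweight; explicit matrices are computed
#' lazily and cached.
#'
#' @param name Basis name, one of [cs_bases()] (`"w"` is accepted as an alias
#'   for `"wtransform"`).
#' @param N Signal length (integer, at least 2).
#' @param variant W-transform variant, one of `"IV"` (default), `"I"`,
#'   `"II"`, `"III"` — the four members of Wang's generalized discrete
#'   W family with kernel `sqrt(2/N) sin(pi/4 + 2 pi (k+u)(n+v) / N)` and
#'   shifts `(u, v)` in `{0, 1/2}^2`.  Type I coincides with the discrete
#'   Hartley transform; type IV (half-sample shifts in both indices) is the
#'   default so that the W column of a basis comparison is distinct from the
#'   DHT column.  Ignored for other bases.
#' @return An object of class `cs_basis` with fields `name`, `N`,
#'   `variant` and `orthonormal` (always `TRUE` for built-ins).
#' @details Coefficient position `i` (1-based, R convention) corresponds to
#'   frequency index `i - 1`; position 1 is DC where the basis has a DC atom.
#' @examples
#' b <- build_basis("dct", 64)
#' x <- cos(pi * 3 * (2 * (0:63) + 1) / 128)
#' s <- analyze(b, x)
#' max(abs(synthesize(b, s) - x)) < 1e-12
#' @export
build_basis <- function(name, N, variant = c("IV", "I", "II", "III")) {
  if (!is.character(name) || length(name) != 1L) {
    cspa_stop("`name` must be a single basis name", "cspa_unsupported_basis")
  }
  if (identical(name, "w")) name <- "wtransform"
  if (!name %in% CS_BASES) {
    cspa_stop(sprintf("unsupported basis '%s' (supported: %s)",
                      name, paste(CS_BASES, collapse = ", ")),
              "cspa_unsupported_basis")
  }
  N <- check_count(N, "N", min = 2L)
  variant <- match.arg(variant)
  structure(
    list(name = name, N = N,
         variant = if (name == "wtransform") variant else NA_character_,
         orthonormal = TRUE,
         cache = new.env(parent = emptyenv())),
    class = "cs_basis")
}

#' @export
print.cs_basis <- function(x, ...) {
  v <- if (is.na(x$variant)) "" else sprintf(" (variant %s)", x$variant)
  cat(sprintf("<cs_basis> %s%s, N = %d, orthonormal\n", x$name, v, x$N))
  invisible(x)
}

check_basis <- function(basis) {
  if (!inherits(basis, "cs_basis")) {
    cspa_stop("`basis` must be a cs_basis object (see build_basis())",
              "cspa_unsupported_basis")
  }
  basis
}

# ---- explicit matrices ------------------------------------------------------

# Analysis matrix for the W family (row k, column n), orthonormal for all
# four shift combinations.
w_analysis_matrix <- function(N, variant) {
  uv <- switch(variant,
               I   = c(0, 0),
               II  = c(0.5, 0),
               III = c(0, 0.5),
               IV  = c(0.5, 0.5))
  sqrt(2 / N) * outer(0:(N - 1), 0:(N - 1), function(k, n) {
    sin(pi / 4 + 2 * pi * (k + uv[1]) * (n + uv[2]) / N)
  })
}

#' Explicit synthesis matrix of a basis
#'
#' Returns the N x N matrix `Psi` such that `x = Psi %*% s`.  For the Fourier
#' basis this is complex (unitary DFT); all other built-ins are real
#' orthogonal.  Used for inspection, export, and cross-checking the fast
#' transform paths.
#'
#' @param basis A `cs_basis`.
#' @return An `N x N` numeric or complex matrix with orthonormal columns.
#' @export
basis_matrix <- function(basis) {
  check_basis(basis)
  if (!is.null(basis$cache$Psi)) return(basis$cache$Psi)
  N <- basis$N
  idx <- 0:(N - 1)
  Psi <- switch(
    basis$name,
    fft = outer(idx, idx, function(n, k) exp(2i * pi * n * k / N)) / sqrt(N),
    dct = {
      C <- sqrt(2 / N) * outer(idx, idx, function(k, n) {
        cos(pi * k * (2 * n + 1) / (2 * N))
      })
      C[1, ] <- C[1, ] / sqrt(2)
      t(C)
    },
    dst = sqrt(2 / (N + 1)) * outer(1:N, 1:N, function(k, n) {
      sin(pi * k * n / (N + 1))
    }),
    dht = outer(idx, idx, function(k, n) {
      a <- 2 * pi * k * n / N
      (cos(a) + sin(a)) / sqrt(N)
    }),
    wtransform = t(w_analysis_matrix(N, basis$variant)))
  basis$cache$Psi <- Psi
  Psi
}

# ---- fast transform kernels -------------------------------------------------

fft_analysis <- function(x) stats::fft(x) / sqrt(length(x))
fft_synthesis <- function(s) stats::fft(s, inverse = TRUE) / sqrt(length(s))

dht_apply <- function(x) {
  # cas kernel via one FFT: sum x (cos + sin) = Re(F) - Im(F); self-inverse.
  F <- stats::fft(x)
  (Re(F) - Im(F)) / sqrt(length(x))
}

# Orthonormal DCT-II through an N-point FFT of the even-odd reordered signal
# (valid for even and odd N).
dct2_analysis <- function(x) {
  N <- length(x)
  v <- c(x[seq(1, N, 2)], rev(x[seq.int(2, length.out = N %/% 2, by = 2)]))
  k <- 0:(N - 1)
  X <- Re(exp(-1i * pi * k / (2 * N)) * stats::fft(v))
  s <- X * sqrt(2 / N)
  s[1] <- s[1] / sqrt(2)
  s
}

dct2_synthesis <- function(s) {
  N <- length(s)
  X <- s
  X[1] <- X[1] * sqrt(2)
  X <- X / sqrt(2 / N)
  k <- 0:(N - 1)
  G <- complex(real = X, imaginary = -c(0, rev(X[-1])))
  v <- Re(stats::fft(exp(1i * pi * k / (2 * N)) * G, inverse = TRUE) / N)
  x <- numeric(N)
  h <- ceiling(N / 2)
  x[seq(1, N, 2)] <- v[1:h]
  if (N > 1) x[seq.int(2, length.out = N %/% 2, by = 2)] <- rev(v[(h + 1):N])
  x
}

# DST-I via odd extension to length 2(N+1); self-inverse.
dst1_apply <- function(x) {
  N <- length(x)
  y <- c(0, x, 0, -rev(x))
  -Im(stats::fft(y))[2:(N + 1)] * sqrt(2 / (N + 1)) / 2
}

# W-transform type IV via a modulated FFT; symmetric and self-inverse.
w4_apply <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  u <- stats::fft(x * exp(1i * pi * n / N), inverse = TRUE)
  Re((1 - 1i) * exp(1i * pi * (2 * n + 1) / (2 * N)) * u) / sqrt(N)
}

# ---- analyze / synthesize ---------------------------------------------------

#' Analyze a signal into basis coefficients
#'
#' Computes the coefficient vector `s = Psi^H x` of `x` in the given basis.
#' For orthonormal bases the coefficient l2 norm equals the signal l2 norm
#' (Parseval) and [synthesize()] inverts the operation exactly (to numerical
#' precision).
#'
#' @param basis A `cs_basis` whose size matches `length(x)`.
#' @param x Real signal (numeric vector of length `basis$N`).
#' @return Coefficient vector of length `N`; complex for the Fourier basis,
#'   numeric otherwise.  Carries the basis name in attribute `basis_name`.
#' @export
analyze <- function(basis, x) {
  check_basis(basis)
  check_signal(x)
  if (length(x) != basis$N) {
    cspa_stop(sprintf("signal length %d does not match basis size %d",
                      length(x), basis$N), "cspa_dimension_error")
  }
  s <- switch(
    basis$name,
    fft = fft_analysis(x),
    dct = dct2_analysis(x),
    dst = dst1_apply(x),
    dht = dht_apply(x),
    wtransform = {
      if (basis$variant == "IV") w4_apply(x)
      else if (basis$variant == "I") dht_apply(x)
      else drop(crossprod(Conj(basis_matrix(basis)), x))
    })
  structure(s, basis_name = basis$name)
}

#' Synthesize a signal from basis coefficients
#'
#' Computes `x = Psi %*% s`, the inverse of [analyze()].  When `s` came from
#' a real signal the numerically negligible imaginary residue (Fourier basis)
#' is dropped and a numeric vector is returned; a genuinely complex result
#' (e.g. a single Fourier atom) is returned as a complex vector.
#'
#' @param basis A `cs_basis` whose size matches `length(s)`.
#' @param s Coefficient vector of length `basis$N`.
#' @return Signal of length `N` (numeric, or complex for non-symmetric
#'   Fourier coefficients).
#' @export
synthesize <- function(basis, s) {
  check_basis(basis)
  check_signal(s, "s")
  if (length(s) != basis$N) {
    cspa_stop(sprintf("coefficient length %d does not match basis size %d",
                      length(s), basis$N), "cspa_dimension_error")
  }
  bn <- attr(s, "basis_name")
  if (!is.null(bn) && !identical(bn, basis$name)) {
    cspa_stop(sprintf("coefficients were produced by basis '%s', not '%s'",
                      bn, basis$name), "cspa_dimension_error")
  }
  s <- as.vector(s)
  x <- switch(
    basis$name,
    fft = fft_synthesis(s),
    dct = {
      if (is.complex(s)) drop(basis_matrix(basis) %*% s) else dct2_synthesis(s)
    },
    dst = dst1_apply(s),
    dht = dht_apply(s),
    wtransform = {
      if (basis$variant == "IV") w4_apply(s)
      else if (basis$variant == "I") dht_apply(s)
      else drop(basis_matrix(basis) %*% s)
    })
  maybe_real(x)
}
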