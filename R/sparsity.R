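# Threshold-based sparsity measurement and basis comparison.
#
# A coefficient vector is profiled by counting how many coefficients survive
# a magnitude threshold c: coefficients strictly smaller than the effective
# threshold are regarded as zero, coefficients equal to it survive.  In
# relative mode (the default) the effective threshold is c * max|s|, which
# makes the count scale-invariant and lets the same c be compared across
# signals of very different amplitude and length.

check_threshold <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    cspa_stop("threshold `c` must be a single positive number",
              "cspa_invalid_threshold")
  }
  c
}

effective_threshold <- function(mag, c, mode) {
  if (mode == "relative") c * max(mag) else c
}

#' Count above-threshold coefficients
#'
#' Number of coefficients whose magnitude is at least the effective
#' threshold.  In `"relative"` mode the effective threshold is
#' `c * max(|s|)`; in `"absolute"` mode it is `c` itself.  An all-zero
#' vector has count 0 in either mode.
#'
#' @param s Coefficient vector (numeric or complex).
#' @param c Positive threshold.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return Non-negative integer count.
#' @export
sparsity_count <- function(s, c, mode = c("relative", "absolute")) {
  check_signal(s, "s")
  check_threshold(c)
  mode <- match.arg(mode)
  mag <- Mod(s)
  if (max(mag) == 0) return(0L)
  sum(mag >= effective_threshold(mag, c, mode))
}

#' Hard-threshold a coefficient vector
#'
#' Sets coefficients with magnitude strictly below the effective threshold
#' to exactly zero (equality survives).  The number of nonzeros in the
#' result equals [sparsity_count()] with the same arguments; the operation
#' is idempotent.
#'
#' @inheritParams sparsity_count
#' @return Thresholded coefficient vector, same type and attributes as `s`.
#' @export
hard_threshold <- function(s, c, mode = c("relative", "absolute")) {
  check_signal(s, "s")
  check_threshold(c)
  mode <- match.arg(mode)
  mag <- Mod(s)
  if (max(mag) == 0) return(s)
  out <- s
  out[mag < effective_threshold(mag, c, mode)] <- 0
  out
}

basis_display <- c(fft = "FFT", dct = "DCT", dst = "DST",
                   dht = "DHT", wtransform = "W")

#' Sparsity profile of a signal across bases and thresholds
#'
#' Decomposes `x` under each requested basis and counts surviving
#' coefficients at each threshold, producing the classic
#' thresholds-by-bases comparison table (rows `c = 0.01, 0.05, 0.1`,
#' columns FFT, DCT, DST, DHT, W by default).  Counts are non-increasing
#' down each column as `c` grows.
#'
#' @param x Real signal.
#' @param bases Character vector of basis names (default: all five).
#' @param thresholds Positive thresholds, default `c(0.01, 0.05, 0.1)`.
#' @param mode Threshold mode, `"relative"` (default) or `"absolute"`.
#' @param label Free-text label recorded on the profile.
#' @return A `sparsity_profile` data frame: first column `c`, one integer
#'   column per basis (display names FFT/DCT/DST/DHT/W).
#' @export
sparsity_profile <- function(x, bases = cs_bases(),
                             thresholds = c(0.01, 0.05, 0.1),
                             mode = c("relative", "absolute"),
                             label = "signal") {
  check_signal(x)
  mode <- match.arg(mode)
  for (ci in thresholds) check_threshold(ci)
  N <- length(x)
  counts <- vapply(bases, function(b) {
    s <- analyze(build_basis(b, N), x)
    vapply(thresholds, function(ci) as.integer(sparsity_count(s, ci, mode)),
           integer(1))
  }, integer(length(thresholds)))
  counts <- matrix(counts, nrow = length(thresholds),
                   dimnames = list(NULL, unname(basis_display[bases])))
  out <- data.frame(c = thresholds, counts, check.names = FALSE)
  structure(out, class = c("sparsity_profile", "data.frame"),
            signal_label = label, mode = mode, N = N)
}

#' @export
print.sparsity_profile <- function(x, ...) {
  cat(sprintf("Sparsity profile of '%s' (N = %d, %s thresholds)\n",
              attr(x, "signal_label"), attr(x, "N"), attr(x, "mode")))
  df <- as.data.frame(x)
  df$c <- sprintf("c=%g", df$c)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Best K-term approximation of a coefficient vector
#'
#' Retains the `K` largest-magnitude coefficients (ties broken toward the
#' lowest index) and reports the relative l2 error of the resulting
#' approximation.  For an orthonormal basis the coefficient-domain error
#' equals the signal-domain error of the synthesized approximation
#' (Parseval), and this greedy selection is the optimal K-sparse
#' approximation.
#'
#' @param s Coefficient vector.
#' @param K Number of coefficients to retain, `0 <= K <= length(s)`.
#' @return A list of class `ks_approx`: `K`, `retained_support` (1-based
#'   positions, at most `K`), `relative_l2_error`, and `s_k` (the K-sparse
#'   coefficient vector).
#' @export
best_k_approx <- function(s, K) {
  check_signal(s, "s")
  N <- length(s)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K != round(K) ||
      K < 0 || K > N) {
    cspa_stop(sprintf("`K` must be an integer in [0, %d]", N), "cspa_invalid_k")
  }
  K <- as.integer(K)
  mag <- Mod(s)
  ord <- order(-mag, seq_len(N))      # stable: ties keep the lowest index
  keep <- sort(ord[seq_len(K)])
  s_k <- s
  s_k[setdiff(seq_len(N), keep)] <- 0
  total <- l2norm(s)
  err <- if (total == 0) 0 else l2norm(s - s_k) / total
  structure(list(K = K, retained_support = keep,
                 relative_l2_error = err, s_k = s_k),
            class = "ks_approx")
}

#' @export
print.ks_approx <- function(x, ...) {
  cat(sprintf("<ks_approx> K = %d, relative l2 error = %.3e\n",
              x$K, x$relative_l2_error))
  invisible(x)
}
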