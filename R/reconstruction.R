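# Sparse recovery: the l0 program min ||s||_0 s.t. y = Phi Psi s and its l1
# relaxation min 1/2 ||y - Phi Psi s||_2^2 + lambda ||s||_1.
#
# Solvers operate on the combined operator A = Phi Psi.  For the complex
# Fourier basis the problem is realified: real and imaginary parts of s are
# stacked as 2N real unknowns with A = [Phi Re(Psi), -Phi Im(Psi)], and the
# reconstructed signal is Re(Psi s).  All solvers are deterministic;
# correlation ties in OMP go to the lowest index.

# Combined sensing operator with realification bookkeeping.
sensing_operator <- function(phi, basis) {
  if (inherits(basis, "cs_basis")) {
    Psi <- basis_matrix(basis)
  } else if (is.matrix(basis)) {
    Psi <- basis
  } else {
    cspa_stop("`basis` must be a cs_basis or a matrix", "cspa_unsupported_basis")
  }
  N <- ncol(Psi)
  check_phi(phi, nrow(Psi))
  phi <- unclass(phi)
  if (is.complex(Psi)) {
    A <- cbind(phi %*% Re(Psi), -(phi %*% Im(Psi)))
    list(A = A, N = N, complex = TRUE, Psi = Psi,
         to_coeffs = function(sr) complex(real = sr[1:N],
                                          imaginary = sr[(N + 1):(2 * N)]))
  } else {
    list(A = phi %*% Psi, N = N, complex = FALSE, Psi = Psi,
         to_coeffs = function(sr) sr)
  }
}

reconstruction_result <- function(op, phi, y, sr, solver, iterations,
                                  objective_trace, converged = TRUE,
                                  debiased = FALSE) {
  s_hat <- op$to_coeffs(sr)
  x_raw <- drop(op$Psi %*% s_hat)
  x_hat <- if (is.complex(x_raw)) Re(x_raw) else x_raw
  structure(
    list(x_hat = x_hat,
         s_hat = s_hat,
         support = which(Mod(s_hat) > 0),
         residual_l2 = l2norm(y - drop(unclass(phi) %*% x_hat)),
         iterations = iterations,
         objective_trace = objective_trace,
         solver = solver,
         converged = converged,
         debiased = debiased),
    class = "cs_reconstruction")
}

#' @export
print.cs_reconstruction <- function(x, ...) {
  cat(sprintf("<cs_reconstruction> solver = %s, |support| = %d, residual = %.3e, %d iterations%s\n",
              x$solver, length(x$support), x$residual_l2, x$iterations,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

ls_on_support <- function(A, S, y) {
  b <- qr.coef(qr(A[, S, drop = FALSE]), y)
  b[is.na(b)] <- 0
  b
}

#' Orthogonal matching pursuit
#'
#' Greedy solver for the l0 recovery problem: at each step the atom of
#' `A = Phi Psi` most correlated with the current residual is added to the
#' support (ties to the lowest index) and the coefficients are refit by
#' least squares on the support.  Stops after `K` atoms or when the residual
#' l2 norm drops to `tol`.
#'
#' @param y Measurement vector (length `M`).
#' @param phi Measurement matrix (`M x N`).
#' @param basis A `cs_basis` (or plain dictionary matrix).
#' @param K Maximum number of atoms, `1 <= K <= M`.
#' @param tol Residual l2 norm at which to stop early (default `1e-10`).
#' @return A `cs_reconstruction`: `x_hat`, `s_hat`, `support` (1-based
#'   coefficient positions), `residual_l2`, `iterations`,
#'   `objective_trace` (residual norms per iteration), `solver = "omp"`.
#' @export
omp <- function(y, phi, basis, K, tol = 1e-10) {
  y <- as.numeric(y)
  op <- sensing_operator(phi, basis)
  M <- nrow(op$A)
  if (length(y) != M) {
    cspa_stop(sprintf("y has length %d but phi has %d rows", length(y), M),
              "cspa_dimension_error")
  }
  K <- check_count(K, "K")
  if (K > M) {
    cspa_stop(sprintf("K = %d atoms cannot be fit from M = %d measurements",
                      K, M), "cspa_infeasible_k")
  }
  A <- op$A
  norms <- sqrt(colSums(A^2))
  usable <- norms > 1e-12
  S <- integer(0)
  b <- numeric(0)
  r <- y
  trace <- l2norm(r)
  while (length(S) < K && l2norm(r) > tol) {
    corr <- abs(drop(crossprod(A, r))) / pmax(norms, .Machine$double.xmin)
    corr[!usable] <- -Inf
    if (length(S)) corr[S] <- -Inf
    j <- which.max(corr)              # first maximum: lowest-index tie-break
    if (!is.finite(corr[j])) break
    S <- c(S, j)
    b <- ls_on_support(A, S, y)
    r <- y - drop(A[, S, drop = FALSE] %*% b)
    trace <- c(trace, l2norm(r))
  }
  sr <- numeric(ncol(A))
  sr[S] <- b
  reconstruction_result(op, phi, y, sr, "omp", length(S), trace)
}

# Largest squared singular value of A by power iteration (deterministic start).
spectral_norm_sq <- function(A, iters = 100L) {
  P <- ncol(A)
  v <- seq_len(P) / l2norm(seq_len(P))
  for (i in seq_len(iters)) {
    w <- drop(crossprod(A, A %*% v))
    nw <- l2norm(w)
    if (nw == 0) return(0)
    v <- w / nw
  }
  drop(crossprod(A %*% v))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Proximal-gradient solver for the l1-penalized problem (ISTA / FISTA)
#'
#' Minimizes `1/2 ||y - A s||_2^2 + lambda ||s||_1` with `A = Phi Psi` by
#' iterative soft thresholding with fixed step `1/L`, where `L` is the
#' squared spectral norm of `A` estimated by 100 power iterations plus a 5%
#' safety margin.  With `accelerated = TRUE` the monotone FISTA variant is
#' used, so the objective trace is non-increasing for both solvers.  Stops
#' when the relative objective change falls below `tol`; failure to converge
#' within `max_iter` is flagged on the result, not raised.
#'
#' @inheritParams omp
#' @param lam Positive l1 penalty `lambda`.
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative objective-change stopping tolerance (default `1e-10`).
#' @param accelerated Use monotone FISTA momentum (default `FALSE` = ISTA).
#' @param debias Refit least squares on the recovered support after the l1
#'   solve (default `FALSE`).
#' @return A `cs_reconstruction` with `objective_trace` holding the penalized
#'   objective per iteration and `solver` `"ista"` or `"fista"`.
#' @export
ista_l1 <- function(y, phi, basis, lam, max_iter = 500L, tol = 1e-10,
                    accelerated = FALSE, debias = FALSE) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    cspa_stop("`lam` must be a single positive number", "cspa_invalid_penalty")
  }
  y <- as.numeric(y)
  op <- sensing_operator(phi, basis)
  A <- op$A
  if (length(y) != nrow(A)) {
    cspa_stop(sprintf("y has length %d but phi has %d rows",
                      length(y), nrow(A)), "cspa_dimension_error")
  }
  P <- ncol(A)
  L <- 1.05 * spectral_norm_sq(A)
  if (L == 0) L <- 1
  step <- 1 / L
  obj <- function(s) 0.5 * sum((y - drop(A %*% s))^2) + lam * sum(abs(s))
  prox_step <- function(s) {
    soft_threshold(s - step * drop(crossprod(A, drop(A %*% s) - y)),
                   lam * step)
  }
  s <- numeric(P)
  trace <- obj(s)
  converged <- FALSE
  if (accelerated) {
    # Monotone FISTA: momentum on the prox points, but the kept iterate never
    # increases the objective.
    z <- s; t_k <- 1
    for (it in seq_len(max_iter)) {
      u <- prox_step(z)                       # prox point
      f_u <- obj(u); f_prev <- obj(s)
      s_new <- if (f_u <= f_prev) u else s
      t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
      z <- s_new + (t_k / t_new) * (u - s_new) +
        ((t_k - 1) / t_new) * (s_new - s)
      s <- s_new; t_k <- t_new
      f_new <- min(f_u, f_prev)
      trace <- c(trace, f_new)
      if (abs(trace[it] - f_new) <= tol * max(1, trace[it])) {
        converged <- TRUE
        break
      }
    }
  } else {
    for (it in seq_len(max_iter)) {
      s <- prox_step(s)
      f_new <- obj(s)
      trace <- c(trace, f_new)
      if (abs(trace[it] - f_new) <= tol * max(1, trace[it])) {
        converged <- TRUE
        break
      }
    }
  }
  it <- length(trace) - 1L
  if (debias) {
    S <- which(abs(s) > 0)
    if (length(S) && length(S) <= nrow(A)) {
      s[S] <- ls_on_support(A, S, y)
    }
  }
  reconstruction_result(op, phi, y, s,
                        solver = if (accelerated) "fista" else "ista",
                        iterations = it, objective_trace = trace,
                        converged = converged, debiased = debias)
}

#' @rdname ista_l1
#' @export
fista_l1 <- function(y, phi, basis, lam, max_iter = 500L, tol = 1e-10,
                     debias = FALSE) {
  ista_l1(y, phi, basis, lam, max_iter = max_iter, tol = tol,
          accelerated = TRUE, debias = debias)
}

#' Exhaustive l0 oracle for small instances
#'
#' Exact minimizer of the residual over all supports of size at most `K`,
#' by least squares on every support.  The l0 problem is NP-hard, so this is
#' guarded to `N <= 16`, `K <= 3`; it serves as the ground-truth oracle for
#' testing the practical solvers (its residual can never exceed OMP's).
#' Ties go to the first support in enumeration order (smaller supports
#' first, then lexicographic).
#'
#' @inheritParams omp
#' @param K Maximum support size, `0 <= K <= 3`.
#' @return A `cs_reconstruction` with `solver = "exhaustive_l0"`;
#'   `iterations` is the number of supports evaluated.
#' @export
exhaustive_l0 <- function(y, phi, basis, K) {
  y <- as.numeric(y)
  op <- sensing_operator(phi, basis)
  N <- op$N
  if (!is.numeric(K) || length(K) != 1L || K != round(K) || K < 0) {
    cspa_stop("`K` must be a single non-negative integer", "cspa_invalid_k")
  }
  if (N > 16 || K > 3) {
    cspa_stop(sprintf("exhaustive search guarded to N <= 16 and K <= 3 (got N = %d, K = %d)",
                      N, K), "cspa_instance_too_large")
  }
  A <- op$A
  P <- ncol(A)
  best_sr <- numeric(P)
  best_res <- l2norm(y)                # empty support
  evaluated <- 1L
  for (k in seq_len(K)) {
    supports <- utils::combn(P, k)
    for (i in seq_len(ncol(supports))) {
      S <- supports[, i]
      b <- ls_on_support(A, S, y)
      res <- l2norm(y - drop(A[, S, drop = FALSE] %*% b))
      evaluated <- evaluated + 1L
      if (res < best_res) {
        best_res <- res
        best_sr <- numeric(P)
        best_sr[S] <- b
      }
    }
  }
  reconstruction_result(op, phi, y, best_sr, "exhaustive_l0", evaluated,
                        objective_trace = best_res)
}

#' Recovery quality metrics
#'
#' Compares a reconstruction to the true signal: relative l2 error, PSNR
#' (peak = `max |x_true|`), and support precision/recall against a known
#' true support.  For an all-zero truth the relative error is undefined;
#' the absolute l2 error is reported instead with `absolute_error = TRUE`.
#'
#' @param x_true True signal.
#' @param result A `cs_reconstruction` (or a numeric vector `x_hat`).
#' @param support_true Optional 1-based true coefficient support; omit for
#'   `NA` precision/recall.
#' @return A list of class `recovery_metrics`: `relative_l2_error`,
#'   `psnr_db`, `support_precision`, `support_recall`, `absolute_error`.
#' @export
evaluate_recovery <- function(x_true, result, support_true = NULL) {
  x_hat <- if (inherits(result, "cs_reconstruction")) result$x_hat else as.numeric(result)
  support <- if (inherits(result, "cs_reconstruction")) result$support else integer(0)
  if (length(x_hat) != length(x_true)) {
    cspa_stop("x_true and the reconstruction have different lengths",
              "cspa_dimension_error")
  }
  nt <- l2norm(x_true)
  abs_mode <- nt == 0
  err <- if (abs_mode) l2norm(x_hat) else l2norm(x_hat - x_true) / nt
  mse <- mean((x_hat - x_true)^2)
  peak <- max(abs(x_true))
  psnr <- if (mse == 0) Inf else if (peak == 0) -Inf else 10 * log10(peak^2 / mse)
  if (is.null(support_true)) {
    prec <- NA_real_; rec <- NA_real_
  } else {
    hit <- length(intersect(support, support_true))
    prec <- if (length(support) == 0) as.numeric(length(support_true) == 0) else hit / length(support)
    rec <- if (length(support_true) == 0) 1 else hit / length(support_true)
  }
  structure(list(relative_l2_error = err, psnr_db = psnr,
                 support_precision = prec, support_recall = rec,
                 absolute_error = abs_mode),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("<recovery_metrics> %s l2 error = %.3e, PSNR = %.2f dB, precision = %s, recall = %s\n",
              if (x$absolute_error) "absolute" else "relative",
              x$relative_l2_error, x$psnr_db,
              format(x$support_precision), format(x$support_recall)))
  invisible(x)
}
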