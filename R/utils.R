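# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

l2norm <- function(x) sqrt(sum(Mod(x)^2))

# Typed error: every condition carries a cspa_* class so callers can
# distinguish failure modes without parsing messages.
cspa_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cspa_error")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All stochastic operations in the package
# route through this so identical seeds give bit-identical draws.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_signal <- function(x, what = "x") {
  if (!is.numeric(x) && !is.complex(x)) {
    cspa_stop(sprintf("`%s` must be a numeric vector", what), "cspa_invalid_signal")
  }
  if (length(x) < 1L) {
    cspa_stop(sprintf("`%s` must have length >= 1", what), "cspa_invalid_signal")
  }
  if (any(!is.finite(Mod(x)))) {
    cspa_stop(sprintf("`%s` contains non-finite values", what), "cspa_invalid_signal")
  }
  invisible(x)
}

check_count <- function(n, what = "N", min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n != round(n) || n < min) {
    cspa_stop(sprintf("`%s` must be a single integer >= %d", what, min),
              "cspa_invalid_size")
  }
  as.integer(n)
}

# Drop a numerically negligible imaginary part; keep genuinely complex values.
maybe_real <- function(z, tol = 1e-9) {
  if (!is.complex(z)) return(z)
  scale <- max(1, max(Mod(z)))
  if (max(abs(Im(z))) <= tol * scale) Re(z) else z
}
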