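# Shared test helpers: seeded random signals and K-sparse recovery instances.

rand_signal <- function(N, seed) {
  set.seed(seed)
  stats::rnorm(N)
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / max(sqrt(sum(Mod(b)^2)), .Machine$double.xmin)
}

l2 <- function(x) sqrt(sum(Mod(x)^2))

# Build a K-sparse ground-truth instance: coefficients s (supported on K
# random positions, magnitudes bounded away from 0), signal x = Psi s,
# measurements y = Phi x.
make_ksparse_instance <- function(N, M, K, seed, basis_name = "dct",
                                  ensemble = "gaussian") {
  basis <- build_basis(basis_name, N)
  set.seed(seed)
  support <- sort(sample.int(N, K))
  s <- numeric(N)
  s[support] <- stats::rnorm(K) + sign(stats::rnorm(K))
  x <- synthesize(basis, s)
  phi <- make_measurement_matrix(M, N, ensemble, seed = seed)
  y <- measure(phi, x)
  list(basis = basis, s = s, x = as.numeric(x), support = support,
       phi = phi, y = y)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "cspa", mustWork = TRUE)
}
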