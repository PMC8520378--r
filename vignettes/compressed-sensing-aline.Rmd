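---
title: "Compressed sensing of A-line signals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed sensing of A-line signals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspa)
```

## The problem

Ultrasound and photoacoustic molecular imaging produce long 1-D
radio-frequency records (A-lines).  Compressed sensing replaces dense
sampling with `M ≪ N` random linear measurements `y = Φx`, relying on the
signal being sparse or compressible in some orthonormal transform domain
`Ψ` (`x = Ψs`).  This package covers the full workflow: choosing `Ψ` by
measuring sparsity empirically, building `Φ`, checking incoherence, and
recovering `x` from `y`.

## Sparse bases

Five orthonormal bases are provided.  All satisfy exact round-trip
(`synthesize(analyze(x)) = x`) and Parseval (`‖s‖₂ = ‖x‖₂`) contracts,
which is why orthonormal variants were fixed rather than the many
unnormalized conventions in circulation:

* `fft` — unitary DFT, `Ψ[n,k] = e^{2πi nk/N}/√N`.  Coefficients are
  complex; sparsity and thresholding use the modulus.
* `dct` — orthonormal DCT-II.  Computed in `O(N log N)` via an N-point FFT
  of the even–odd reordered signal (valid for odd and even `N`), with the
  matching inverse.
* `dst` — orthonormal DST-I, `√(2/(N+1)) sin(πkn/(N+1))`; symmetric and
  self-inverse, computed via an odd extension to length `2(N+1)`.
* `dht` — orthonormal discrete Hartley, kernel `cas(2πnk/N)/√N`;
  self-inverse, computed from one FFT.
* `wtransform` — Wang's generalized discrete W family, kernel
  `√(2/N) sin(π/4 + 2π(k+u)(n+v)/N)`, shifts `(u,v) ∈ {0, ½}²` giving
  variants I–IV.  All four are orthonormal.

**Which W variant?**  The type-I kernel satisfies
`sin(π/4 + θ) = cas(θ)/√2`, so type I is *identical* to the Hartley
transform.  Defaulting to it would make a five-basis comparison carry a
duplicate column.  The package therefore defaults to type IV (half-sample
shifts in both indices; symmetric, self-inverse, with its own modulated-FFT
fast path) and exposes the full family through the `variant` argument.

Coefficient position `i` (R's 1-based convention) corresponds to frequency
index `i − 1`; position 1 is DC where the basis has a DC atom.

## Threshold-based sparsity

A coefficient is treated as zero when its magnitude is *strictly below* the
effective threshold; equality survives.  The default mode is **relative**:
the effective threshold is `c · max|s|`.  Thresholds like
`c ∈ {0.01, 0.05, 0.1}` are only comparable across signals of different
lengths and amplitudes as fractions of the peak coefficient, and relative
mode makes the count scale-invariant.  Absolute mode is available for
calibrated data.  `sparsity_profile()` assembles the thresholds-by-bases
count table (rows `c = 0.01, 0.05, 0.1`; columns FFT, DCT, DST, DHT, W),
and `best_k_approx()` reports the optimal K-term approximation error, with
ties in coefficient magnitude broken toward the lowest index for
determinism.

On smooth, baseline-dominated signals the DST column is systematically the
densest: DST-I has no DC atom and forces zero boundary values, so a mean
offset spreads over `O(N)` coefficients with `1/k` decay, while DCT absorbs
it in one atom.  The packaged piecewise-smooth fixtures are generated with
positive per-segment baselines precisely to represent this regime —
envelope-like recordings with a dominant mean — and the test suite asserts
the resulting ordering (DST ≥ DCT at every threshold; DST ≥ FFT in
aggregate over a profile, since single-digit rows differ by counting
noise).

## Sensing

`make_measurement_matrix()` builds Gaussian, Bernoulli (±1) or
row-subsampled-identity ensembles, reproducible per `(ensemble, M, N,
seed)`.  Rows are normalized to unit l2 norm — rather than columns — so
that measurement noise of a given `σ` and coherence values mean the same
thing across ensembles.  Measurement noise is additive i.i.d. Gaussian
with its own seed, kept separate from the matrix seed so experiments can
vary one while fixing the other.  `mutual_coherence()` returns
`√N · max|⟨φ_k, ψ_j⟩|` over unit-normalized rows and columns, which lies in
`[1, √N]`; spike rows against the unitary Fourier basis attain 1.

## Recovery

All solvers act on `A = ΦΨ`.  For the complex Fourier basis the problem is
realified: real and imaginary parts of `s` become `2N` stacked real
unknowns with `A = [Φ Re Ψ, −Φ Im Ψ]`, and the reconstruction is
`Re(Ψ ŝ)`.  This keeps every solver real-valued at the cost of doubling
the atom count.

* **OMP** adds the atom most correlated with the residual (correlations
  normalized by atom norm; zero-norm atoms skipped; ties to the lowest
  index), refits least squares on the support, and stops at `K` atoms or
  residual `≤ tol` (default `1e-10`).
* **ISTA / FISTA** minimize `½‖y − As‖₂² + λ‖s‖₁` by proximal gradient
  with fixed step `1/L`, where `L` is the squared spectral norm of `A`
  from 100 power iterations (deterministic start vector) plus a 5% safety
  margin — guaranteeing descent without a line search.  The accelerated
  variant is *monotone* FISTA: the momentum point is tested against the
  previous iterate and the objective never increases, so the
  non-increasing-trace contract holds for both solvers.  Iteration stops
  when the relative objective change falls below `tol`; non-convergence
  within `max_iter` is flagged on the result, not raised.  An optional
  debias step refits least squares on the recovered support.  The default
  penalty `λ = 0.01` suits the canonical noiseless `N = 300, M = 100,
  K = 5` demonstration, where the converged l1 support is small enough to
  refit; much smaller penalties leave many tiny atoms and the refit is
  skipped.
* **Exhaustive l0 oracle** enumerates every support of size `≤ K`
  (guarded to `N ≤ 16`, `K ≤ 3`) and is the ground truth the practical
  solvers are tested against.  Its residual can never exceed OMP's; note
  that greedy OMP is *not* guaranteed to match the oracle's optimum even
  when unique — on coherent small instances it occasionally picks a wrong
  first atom, which is precisely why the l0 problem is hard.

Rank-deficient least-squares subproblems use QR with unidentified
coefficients set to zero, so degenerate supports (e.g. duplicate atoms
from the realified Fourier conjugate pair) are handled without error.

## The phantom module

`generate_test_signal()` produces three kinds of compressible signals:

* `harmonic_mixture` — cosines on the half-sample (DCT-II) frequency grid
  with seeded frequencies, amplitudes (0.5–1.5) and signs.  The grid
  choice is deliberate: an arbitrary-phase sinusoid is *not* two-atom
  sparse under DCT-II, and the generator's contract is that the noiseless
  mixture is exactly `components`-sparse so recovery experiments have a
  known ground truth.
* `chirp_plus_spikes` — a linear chirp plus seeded isolated spikes.
* `piecewise_smooth` — random quadratic segments with positive baselines
  (see above).

`generate_pa_aline()` models each absorber as the closed-form N-shaped
bipolar pulse of a uniformly heated sphere: amplitude `A·(t − t₀)/τ` for
`|t − t₀| ≤ τ`, with `t₀ = depth/c` and `τ = radius/c`.  Units are mm, µs
and mm/µs; defaults are `c = 1.5 mm/µs` (soft tissue), 20 samples/µs and a
15 µs record (`N = 300`), with three absorbers at 6/12/18 mm.  Absorbers
whose pulse would spill outside the record raise an error rather than
truncate silently.

`simulate_contrast_experiment()` reproduces the three-group design of a
laser-triggered phase-change contrast study: the targeted group's absorber
amplitudes scale by an `enhancement_factor` (default 3) after irradiation,
the blank group is unchanged, and the water control has no absorbers.
Enhancement is modelled purely as amplitude scaling — an explicit knob, not
a physical claim; the underlying experiment reports enhancement only
qualitatively, so the phantom reproduces the design and ordering of the
groups, not calibrated magnitudes.  Noiselessly the post/pre l2 ratio for
the targeted group equals the factor exactly.

**What the phantom does not model:** acoustic propagation and attenuation,
transducer bandwidth and focusing, beamforming, optical fluence, speckle
from diffuse scatterers, and nanoparticle physics.  Passing tests
demonstrate the correctness of the CS machinery on signals with known
structure, not performance on recorded in vivo data.

A consequence worth stating plainly: N-wave pulse trains are sparse *in
time*, not in any of the five transform bases (their best-40-term DCT
approximation of the default A-line still carries ~40% relative error), so
transform-domain CS of a raw A-line is only mildly effective.  The solver
surface accepts plain dictionary matrices, and the test suite demonstrates
exact A-line recovery with the identity (time-domain) dictionary at
`M = 180, K ≈ 33` — choosing a sparse model that matches the signal class
is part of the method.

## Problem sizes and tolerances

The canonical lengths are `N = 300` and `N = 1841`; transform contracts
are verified at `N ∈ {8, 64, 300, 1841}` with round-trip and Parseval
tolerance `1e-9` (observed errors are near machine precision), and
fast-path-versus-explicit-matrix agreement at `N ≤ 32` with tolerance
`1e-10`.  Recovery experiments use the `N = 300, M = 100, K = 5` instance,
an oracle-dominance sweep over 200 instances at `N ∈ 8–12`, and an OMP
success-rate curve over `M ∈ {8, 16, 32, 64}` at `N = 128, K = 4` with 50
seeds per point.  Phantom Monte-Carlo checks use 100 seeds.  These sizes
keep the full suite and the acceptance script within seconds on one CPU
while leaving each property far from its tolerance boundary.

## Known limitations

* 1-D only; 2-D imaging would apply the pipeline row-wise.
* No structured operators (partial Fourier, Toeplitz) and no RIP-constant
  estimation beyond mutual coherence.
* The l1 path has no continuation/warm-start scheme; very small penalties
  converge slowly.
* The W-transform variants II/III (non-symmetric members of the family)
  use cached explicit matrices rather than a fast path.
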