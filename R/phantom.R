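# Synthetic inputs: compressible test signals and photoacoustic A-lines.
#
# Two generators.  generate_test_signal() produces generic compressible
# 1-D signals (harmonic mixtures, chirp-plus-spikes, piecewise-smooth) for
# basis comparison and recovery experiments; the canonical lengths are
# N = 1841 and N = 300.  generate_pa_aline() produces a photoacoustic
# A-line as a superposition of N-shaped bipolar pulses, the closed-form
# pressure response of a uniformly heated spherical absorber: for an
# absorber at depth d (mm) with radius a (mm) in a medium with sound speed
# c (mm/us), the pulse is A * (t - t0)/tau on |t - t0| <= tau with
# t0 = d/c and tau = a/c, zero elsewhere.
# simulate_contrast_experiment() wraps this in the three-group design of a
# laser-triggered phase-change contrast study: targeted particles (AP_GNP)
# whose echo amplitude is enhanced after irradiation, blank particles (NP)
# with no enhancement, and a water control with no absorbers at all.

#' Generate a compressible test signal
#'
#' @param N Signal length (default 300; the companion canonical length is
#'   1841).
#' @param kind `"harmonic_mixture"` (default): a sum of `components` cosines
#'   on the half-sample cosine-transform frequency grid with seeded
#'   frequencies, amplitudes and signs — exactly `components`-sparse under
#'   the DCT-II basis when noiseless.  `"chirp_plus_spikes"`: a linear chirp
#'   plus `components` isolated spikes.  `"piecewise_smooth"`: `components`
#'   quadratic segments with random breakpoints and positive baseline
#'   offsets, emulating envelope-like recordings with a dominant mean
#'   component.
#' @param components Number of harmonics / spikes / segments (default 3).
#' @param snr_db Signal-to-noise ratio in dB of added white Gaussian noise;
#'   `Inf` (default) for a noiseless signal.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return Numeric signal of length `N` with attributes `kind` and `seed`.
#' @export
generate_test_signal <- function(N = 300, kind = c("harmonic_mixture",
                                                   "chirp_plus_spikes",
                                                   "piecewise_smooth"),
                                 components = 3L, snr_db = Inf, seed = 1L) {
  N <- check_count(N, "N", min = 8L)
  if (is.character(kind) && length(kind) == 1L &&
      !kind %in% c("harmonic_mixture", "chirp_plus_spikes", "piecewise_smooth")) {
    cspa_stop(sprintf("unsupported test-signal kind '%s'", kind),
              "cspa_unsupported_kind")
  }
  kind <- match.arg(kind)
  components <- check_count(components, "components")
  n <- 0:(N - 1)
  x <- with_seed(seed, {
    base <- switch(
      kind,
      harmonic_mixture = {
        k <- sample.int(N - 1, min(components, N - 1))
        amp <- stats::runif(length(k), 0.5, 1.5) *
          sample(c(-1, 1), length(k), replace = TRUE)
        colSums(amp * t(sapply(k, function(kk) {
          cos(pi * kk * (2 * n + 1) / (2 * N))
        })))
      },
      chirp_plus_spikes = {
        t <- n / N
        f0 <- stats::runif(1, 2, 10)
        f1 <- stats::runif(1, N / 10, N / 6)
        sig <- cos(2 * pi * (f0 * t + 0.5 * (f1 - f0) * t^2))
        pos <- sample.int(N, min(components, N))
        sig[pos] <- sig[pos] + stats::runif(length(pos), 1, 3) *
          sample(c(-1, 1), length(pos), replace = TRUE)
        sig
      },
      piecewise_smooth = {
        nb <- min(components, N %/% 4)
        br <- sort(c(0L, sample(seq_len(N - 1), max(nb - 1, 0)), N))
        sig <- numeric(N)
        for (i in seq_len(length(br) - 1)) {
          span <- (br[i] + 1):br[i + 1]
          u <- seq(0, 1, length.out = length(span))
          # positive per-segment baseline: emulates envelope-like recordings
          # whose mean offset dominates the spectrum
          cf <- c(stats::runif(1, 0.5, 2.5), stats::runif(2, -1, 1))
          sig[span] <- cf[1] + cf[2] * u + cf[3] * u^2
        }
        sig
      })
    if (is.finite(snr_db)) {
      sigma <- sqrt(mean(base^2)) * 10^(-snr_db / 20)
      base + stats::rnorm(N, 0, sigma)
    } else base
  })
  structure(as.numeric(x), kind = kind, seed = seed)
}

#' Configuration for a photoacoustic A-line phantom
#'
#' @param absorber_positions Absorber depths in mm (may be empty).
#' @param absorber_radii Absorber radii in mm (recycled to match positions).
#' @param absorber_amplitudes Peak pulse amplitudes, arbitrary units
#'   (recycled).
#' @param sound_speed Speed of sound in mm/us (default 1.5, soft tissue).
#' @param sampling_rate Samples per us (default 20).
#' @param duration Record length in us (default 15, i.e. N = 300 samples).
#' @param noise_sigma Additive white-noise standard deviation (default 0.01).
#' @param seed Integer seed for the noise draw.
#' @return A validated list of class `pa_phantom_config`.
#' @export
pa_phantom_config <- function(absorber_positions = c(6, 12, 18),
                              absorber_radii = 0.45,
                              absorber_amplitudes = c(1, 0.8, 0.6),
                              sound_speed = 1.5, sampling_rate = 20,
                              duration = 15, noise_sigma = 0.01, seed = 1L) {
  np <- length(absorber_positions)
  if (np > 0) {
    absorber_radii <- rep_len(absorber_radii, np)
    absorber_amplitudes <- rep_len(absorber_amplitudes, np)
  } else {
    absorber_radii <- numeric(0)
    absorber_amplitudes <- numeric(0)
  }
  if (sound_speed <= 0 || sampling_rate <= 0 || duration <= 0) {
    cspa_stop("sound_speed, sampling_rate and duration must be positive",
              "cspa_invalid_config")
  }
  if (any(absorber_radii <= 0)) {
    cspa_stop("absorber radii must be positive", "cspa_invalid_config")
  }
  if (any(absorber_amplitudes < 0)) {
    cspa_stop("absorber amplitudes must be non-negative", "cspa_invalid_config")
  }
  max_depth <- duration * sound_speed
  if (np > 0 && any(absorber_positions < 0 | absorber_positions > max_depth)) {
    cspa_stop(sprintf("absorber depths must lie in [0, %.3g] mm", max_depth),
              "cspa_out_of_window")
  }
  if (noise_sigma < 0) {
    cspa_stop("noise_sigma must be non-negative", "cspa_invalid_config")
  }
  structure(list(absorber_positions = absorber_positions,
                 absorber_radii = absorber_radii,
                 absorber_amplitudes = absorber_amplitudes,
                 sound_speed = sound_speed, sampling_rate = sampling_rate,
                 duration = duration, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "pa_phantom_config")
}

# Noiseless pulse train for a config (shared by the generators).
pa_pulse_train <- function(config) {
  N <- as.integer(round(config$duration * config$sampling_rate))
  t <- (0:(N - 1)) / config$sampling_rate
  x <- numeric(N)
  for (i in seq_along(config$absorber_positions)) {
    t0 <- config$absorber_positions[i] / config$sound_speed
    tau <- config$absorber_radii[i] / config$sound_speed
    if (t0 - tau < 0 || t0 + tau > config$duration) {
      cspa_stop(sprintf("absorber %d (depth %.3g mm, radius %.3g mm) falls outside the time window",
                        i, config$absorber_positions[i], config$absorber_radii[i]),
                "cspa_out_of_window")
    }
    inside <- abs(t - t0) <= tau
    x[inside] <- x[inside] + config$absorber_amplitudes[i] * (t[inside] - t0) / tau
  }
  x
}

#' Generate a photoacoustic A-line
#'
#' Superposition of N-shaped bipolar pulses (one per absorber in the
#' config) plus seeded white Gaussian noise.  Deterministic per seed.
#'
#' @param config A [pa_phantom_config()].
#' @param seed Noise seed; defaults to `config$seed`.
#' @return Numeric A-line of length `round(duration * sampling_rate)` with
#'   attribute `seed`.
#' @export
generate_pa_aline <- function(config = pa_phantom_config(),
                              seed = config$seed) {
  if (!inherits(config, "pa_phantom_config")) {
    cspa_stop("`config` must be a pa_phantom_config", "cspa_invalid_config")
  }
  x <- pa_pulse_train(config)
  if (config$noise_sigma > 0) {
    x <- x + with_seed(seed, stats::rnorm(length(x), 0, config$noise_sigma))
  }
  structure(x, seed = as.integer(seed))
}

#' Simulate the three-group contrast-enhancement experiment
#'
#' Produces a pre-irradiation and a post-irradiation A-line for one of the
#' three experimental groups: `"AP_GNP"` (targeted phase-change particles —
#' absorber amplitudes scale by `enhancement_factor` after irradiation),
#' `"NP"` (blank particles — no enhancement, post equals pre up to an
#' independent noise draw), `"water"` (no absorbers at all; both records are
#' noise only).  Noiselessly, the post/pre l2-norm ratio for AP_GNP equals
#' the enhancement factor (energy ratio: its square).
#'
#' @param config A [pa_phantom_config()].
#' @param group `"AP_GNP"`, `"NP"` or `"water"`.
#' @param enhancement_factor Amplitude scale applied after irradiation,
#'   `>= 1` (default 3).
#' @param seed Integer seed; pre- and post-noise are drawn sequentially from
#'   one stream, so the pair is deterministic per seed.
#' @return A list of class `contrast_experiment` with fields `group`, `pre`,
#'   `post`, `enhancement_factor`, `seed` and `config`.
#' @export
simulate_contrast_experiment <- function(config = pa_phantom_config(),
                                         group = c("AP_GNP", "NP", "water"),
                                         enhancement_factor = 3, seed = 1L) {
  group <- match.arg(group)
  if (!is.numeric(enhancement_factor) || length(enhancement_factor) != 1L ||
      !is.finite(enhancement_factor) || enhancement_factor < 1) {
    cspa_stop("`enhancement_factor` must be a single number >= 1",
              "cspa_invalid_factor")
  }
  if (group == "NP") enhancement_factor <- 1
  base_cfg <- config
  if (group == "water") {
    base_cfg <- pa_phantom_config(absorber_positions = numeric(0),
                                  sound_speed = config$sound_speed,
                                  sampling_rate = config$sampling_rate,
                                  duration = config$duration,
                                  noise_sigma = config$noise_sigma,
                                  seed = config$seed)
  }
  pulse_pre <- pa_pulse_train(base_cfg)
  pulse_post <- if (group == "AP_GNP") enhancement_factor * pulse_pre else pulse_pre
  noise <- function(n) {
    if (base_cfg$noise_sigma > 0) stats::rnorm(n, 0, base_cfg$noise_sigma) else 0
  }
  N <- length(pulse_pre)
  signals <- with_seed(seed, list(pre = pulse_pre + noise(N),
                                  post = pulse_post + noise(N)))
  structure(list(group = group, pre = signals$pre, post = signals$post,
                 enhancement_factor = enhancement_factor,
                 seed = as.integer(seed), config = base_cfg),
            class = "contrast_experiment")
}

#' @export
print.contrast_experiment <- function(x, ...) {
  cat(sprintf("<contrast_experiment> group = %s, factor = %g, N = %d, post/pre l2 ratio = %.3f\n",
              x$group, x$enhancement_factor, length(x$pre),
              l2norm(x$post) / max(l2norm(x$pre), .Machine$double.eps)))
  invisible(x)
}
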