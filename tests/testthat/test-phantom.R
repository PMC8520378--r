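# Synthetic signal generators: compressibility contracts, the N-wave A-line
# model, and the three-group contrast experiment.

test_that("generators are deterministic per seed", {
  for (kind in c("harmonic_mixture", "chirp_plus_spikes", "piecewise_smooth")) {
    a <- generate_test_signal(128, kind, components = 3, seed = 42)
    b <- generate_test_signal(128, kind, components = 3, seed = 42)
    d <- generate_test_signal(128, kind, components = 3, seed = 43)
    expect_identical(as.numeric(a), as.numeric(b))
    expect_false(identical(as.numeric(a), as.numeric(d)))
  }
  cfg <- pa_phantom_config()
  expect_identical(as.numeric(generate_pa_aline(cfg)),
                   as.numeric(generate_pa_aline(cfg)))
  expect_error(generate_test_signal(64, "sawtooth"),
               class = "cspa_unsupported_kind")
})

test_that("noiseless harmonic mixtures satisfy the compressibility contracts", {
  b300 <- build_basis("dct", 300)
  for (seed in 1:10) {
    x <- generate_test_signal(300, "harmonic_mixture", components = 3,
                              seed = seed)
    s <- analyze(b300, x)
    # exactly sparse: best 2K-term error negligible
    expect_lt(best_k_approx(s, 6)$relative_l2_error, 1e-6)
    # profile-level sparsity at relative c = 0.1
    expect_lte(sparsity_count(s, 0.1), 12)
    # compressible at K = N/10
    expect_lt(best_k_approx(s, 30)$relative_l2_error, 0.1)
  }
  # the paper-scale default length builds and profiles without error
  x <- generate_test_signal(1841, "harmonic_mixture", components = 5, seed = 1)
  p <- sparsity_profile(x)
  expect_equal(nrow(p), 3L)
  # additive noise moves the signal by roughly the requested SNR
  xn <- generate_test_signal(300, "harmonic_mixture", components = 3,
                             snr_db = 20, seed = 4)
  x0 <- generate_test_signal(300, "harmonic_mixture", components = 3,
                             seed = 4)
  snr_est <- 20 * log10(l2(x0) / l2(xn - x0))
  expect_gt(snr_est, 15); expect_lt(snr_est, 25)
})

test_that("A-lines are N-wave superpositions with correct timing", {
  # zero absorbers, zero noise -> identically zero
  empty <- pa_phantom_config(absorber_positions = numeric(0), noise_sigma = 0)
  expect_equal(max(abs(generate_pa_aline(empty))), 0)

  # one absorber at 15 mm depth, c = 1.5 mm/us -> pulse centred at t0 = 10 us
  one <- pa_phantom_config(absorber_positions = 15, absorber_radii = 0.45,
                           absorber_amplitudes = 1, noise_sigma = 0)
  x <- as.numeric(generate_pa_aline(one))
  t <- (seq_along(x) - 1) / one$sampling_rate
  on_support <- which(x != 0)
  expect_true(all(abs(t[on_support] - 10) <= 0.3 + 1e-12))   # tau = 0.3 us
  # bipolar N shape: negative leading lobe, positive trailing lobe
  expect_lt(x[min(on_support)], 0)
  expect_gt(x[max(on_support)], 0)

  # superposition: two absorbers equal the sum of the singles (noiseless)
  a <- pa_phantom_config(absorber_positions = 6, absorber_radii = 0.45,
                         absorber_amplitudes = 1, noise_sigma = 0)
  b <- pa_phantom_config(absorber_positions = 12, absorber_radii = 0.6,
                         absorber_amplitudes = 0.7, noise_sigma = 0)
  ab <- pa_phantom_config(absorber_positions = c(6, 12),
                          absorber_radii = c(0.45, 0.6),
                          absorber_amplitudes = c(1, 0.7), noise_sigma = 0)
  expect_equal(as.numeric(generate_pa_aline(ab)),
               as.numeric(generate_pa_aline(a)) + as.numeric(generate_pa_aline(b)),
               tolerance = 1e-12)

  # absorber whose pulse spills out of the record is rejected
  late <- pa_phantom_config(absorber_positions = 22.4, absorber_radii = 0.45,
                            absorber_amplitudes = 1, noise_sigma = 0)
  expect_error(generate_pa_aline(late), class = "cspa_out_of_window")
  expect_error(pa_phantom_config(absorber_positions = 30),
               class = "cspa_out_of_window")
})

test_that("contrast experiment groups behave as designed", {
  cfg0 <- pa_phantom_config(noise_sigma = 0)
  # AP_GNP: post/pre l2 ratio equals the enhancement factor exactly
  ex <- simulate_contrast_experiment(cfg0, "AP_GNP", enhancement_factor = 3)
  expect_equal(l2(ex$post) / l2(ex$pre), 3, tolerance = 1e-12)
  # NP: no enhancement; noiselessly post equals pre
  ex <- simulate_contrast_experiment(cfg0, "NP", enhancement_factor = 3)
  expect_equal(ex$enhancement_factor, 1)
  expect_equal(ex$post, ex$pre)
  # water: no absorbers, only noise
  cfg <- pa_phantom_config(noise_sigma = 0.01)
  ex <- simulate_contrast_experiment(cfg, "water", seed = 5)
  expect_lt(max(abs(ex$pre)), 0.01 * 6)    # pure noise stays within ~6 sigma
  expect_error(simulate_contrast_experiment(cfg, "AP_GNP",
                                            enhancement_factor = 0.5),
               class = "cspa_invalid_factor")
})

test_that("water-group energy matches the noise floor across seeds", {
  cfg <- pa_phantom_config(noise_sigma = 0.01)
  N <- round(cfg$duration * cfg$sampling_rate)
  energies <- sapply(1:100, function(s) {
    sum(simulate_contrast_experiment(cfg, "water", seed = s)$post^2)
  })
  # mean energy ~ N * sigma^2
  expect_equal(mean(energies), N * 0.01^2, tolerance = 0.1)
})

test_that("post-irradiation energy orders AP_GNP > NP > water across seeds", {
  cfg <- pa_phantom_config(noise_sigma = 0.01)
  post_energy <- function(group) {
    mean(sapply(1:30, function(s) {
      sum(simulate_contrast_experiment(cfg, group, enhancement_factor = 3,
                                       seed = s)$post^2)
    }))
  }
  e <- c(AP_GNP = post_energy("AP_GNP"), NP = post_energy("NP"),
         water = post_energy("water"))
  expect_gt(e["AP_GNP"], e["NP"])
  expect_gt(e["NP"], e["water"])
})
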