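# End-to-end demonstration pipeline: phantom -> sense -> reconstruct ->
# evaluate, with a JSON run summary recording every seed and parameter.

#' Pipeline configuration
#'
#' Defaults describe the canonical demonstration: a noiseless 5-component
#' harmonic mixture of length 300 (5-sparse in the DCT basis), sensed by a
#' seeded Gaussian matrix with M = 100 measurements, reconstructed by OMP
#' with K = 5.
#'
#' @param N Signal length.
#' @param kind Test-signal kind (see [generate_test_signal()]), or
#'   `"pa_aline"` to use the photoacoustic phantom.
#' @param components Number of signal components.
#' @param snr_db Phantom SNR in dB (`Inf` = noiseless).
#' @param basis Sparse basis name.
#' @param M Number of measurements.
#' @param ensemble Measurement ensemble.
#' @param noise_sigma Measurement-noise standard deviation.
#' @param solver `"omp"`, `"ista"` or `"fista"`.
#' @param K OMP sparsity level.
#' @param lam l1 penalty for ISTA/FISTA.
#' @param debias Debias ISTA/FISTA solutions by least squares on the support.
#' @param seed Global seed (phantom, matrix and noise seeds derive from it).
#' @param out_dir Directory for artifacts (`NULL`: nothing written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(N = 300, kind = "harmonic_mixture",
                            components = 5L, snr_db = Inf, basis = "dct",
                            M = 100, ensemble = "gaussian", noise_sigma = 0,
                            solver = "omp", K = 5L, lam = 1e-2,
                            debias = TRUE, seed = 7L, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_log <- function(quiet, stage, msg) {
  if (!quiet) message(sprintf("[cspa:%s] %s", stage, msg))
}

#' Run the phantom -> sense -> reconstruct -> evaluate pipeline
#'
#' Each stage is executed in order; a failure is logged to stderr with the
#' stage name and turns into a nonzero status rather than an R error.  When
#' `config$out_dir` is set, the phantom signal, measurements, reconstruction
#' and a JSON summary (seeds, parameters, metrics) are written there.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `status` (0 = success), `metrics`
#'   ([evaluate_recovery()] output), `result` (the reconstruction), `x`
#'   (the phantom signal) and `summary` (the run summary list).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stage <- "setup"
  out <- tryCatch({
    stage <- "phantom"
    x <- if (identical(config$kind, "pa_aline")) {
      cfg <- pa_phantom_config(noise_sigma = 0, seed = config$seed)
      as.numeric(generate_pa_aline(cfg))
    } else {
      as.numeric(generate_test_signal(config$N, config$kind,
                                      config$components, config$snr_db,
                                      seed = config$seed))
    }
    pipeline_log(quiet, stage, sprintf("generated %s signal, N = %d",
                                       config$kind, length(x)))

    stage <- "basis"
    basis <- build_basis(config$basis, length(x))
    s_true <- analyze(basis, x)
    mag <- Mod(s_true)
    support_true <- which(mag > 1e-8 * max(mag))

    stage <- "sense"
    phi <- make_measurement_matrix(config$M, length(x), config$ensemble,
                                   seed = config$seed)
    y <- measure(phi, x, config$noise_sigma, seed = config$seed + 1L)
    pipeline_log(quiet, stage,
                 sprintf("M = %d %s measurements (noise sigma = %g)",
                         config$M, config$ensemble, config$noise_sigma))

    stage <- "reconstruct"
    result <- switch(config$solver,
                     omp = omp(y, phi, basis, K = config$K),
                     ista = ista_l1(y, phi, basis, lam = config$lam,
                                    debias = config$debias),
                     fista = fista_l1(y, phi, basis, lam = config$lam,
                                      debias = config$debias),
                     cspa_stop(sprintf("unknown solver '%s'", config$solver),
                               "cspa_invalid_config"))
    pipeline_log(quiet, stage,
                 sprintf("%s: %d iterations, residual %.3e",
                         result$solver, result$iterations, result$residual_l2))

    stage <- "evaluate"
    metrics <- evaluate_recovery(x, result, support_true)
    pipeline_log(quiet, stage,
                 sprintf("relative l2 error %.3e, PSNR %.1f dB",
                         metrics$relative_l2_error, metrics$psnr_db))

    summary <- list(
      package = "cspa",
      version = as.character(utils::packageVersion("cspa")),
      config = config[setdiff(names(config), "out_dir")],
      seeds = list(global = config$seed, phantom = config$seed,
                   matrix = config$seed, noise = config$seed + 1L),
      metrics = list(relative_l2_error = metrics$relative_l2_error,
                     psnr_db = metrics$psnr_db,
                     support_precision = metrics$support_precision,
                     support_recall = metrics$support_recall),
      solver = list(name = result$solver, iterations = result$iterations,
                    residual_l2 = result$residual_l2,
                    support_size = length(result$support)))

    if (!is.null(config$out_dir)) {
      stage <- "write"
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      meta <- list(seed = config$seed, kind = config$kind, N = length(x))
      write_signal(x, file.path(config$out_dir, "signal.txt"), metadata = meta)
      write_signal(as.numeric(y), file.path(config$out_dir, "measurements.txt"),
                   metadata = list(seed = config$seed, M = config$M,
                                   ensemble = config$ensemble,
                                   matrix_seed = config$seed,
                                   noise_seed = config$seed + 1L,
                                   noise_sigma = config$noise_sigma))
      write_signal(result$x_hat,
                   file.path(config$out_dir, "reconstruction.txt"),
                   metadata = list(solver = result$solver, seed = config$seed))
      jsonlite::write_json(summary,
                           file.path(config$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
    }
    list(status = 0L, metrics = metrics, result = result, x = x,
         summary = summary)
  }, error = function(e) {
    message(sprintf("[cspa:%s] ERROR: %s", stage, conditionMessage(e)))
    list(status = 1L, error = conditionMessage(e), stage = stage)
  })
  invisible(out)
}
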