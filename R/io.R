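# File formats: signals as delimited text (one sample per line, '#'
# comments) or R's native binary serialization (RDS); sparsity profiles and
# metrics as CSV; matrices as whitespace-delimited text.  Text artifacts
# carry their provenance (seed, parameters) as '# key: value' header
# comments so a run can be reproduced from the file alone.

#' Read a 1-D signal from a file
#'
#' @param path File path.
#' @param format `"text"`: one sample per line, `#` starts a comment, blank
#'   lines ignored; `"rds"`: R's binary serialization (lossless round-trip).
#' @return Numeric signal vector.
#' @export
read_signal <- function(path, format = c("text", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    cspa_stop(sprintf("input file '%s' does not exist", path), "cspa_io_error")
  }
  if (format == "rds") {
    x <- readRDS(path)
    check_signal(x)
    return(x)
  }
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(stripped))
  if (length(keep) == 0) {
    cspa_stop(sprintf("'%s' contains no samples", path), "cspa_empty_input")
  }
  vals <- suppressWarnings(as.numeric(stripped[keep]))
  bad <- which(is.na(vals))
  if (length(bad)) {
    cspa_stop(sprintf("cannot parse '%s' as a number on line %d of '%s'",
                      stripped[keep][bad[1]], keep[bad[1]], path),
              "cspa_parse_error")
  }
  vals
}

#' Write a 1-D signal to a file
#'
#' @param x Numeric signal.
#' @param path Output path.
#' @param format `"text"` or `"rds"` (see [read_signal()]).
#' @param metadata Named list written as `# key: value` header comments
#'   (text format only).
#' @export
write_signal <- function(x, path, format = c("text", "rds"), metadata = NULL) {
  format <- match.arg(format)
  check_signal(x)
  if (format == "rds") {
    saveRDS(as.numeric(x), path)
    return(invisible(path))
  }
  header <- character(0)
  if (length(metadata)) {
    header <- sprintf("# %s: %s", names(metadata),
                      vapply(metadata, function(v) paste(format(v), collapse = " "),
                             character(1)))
  }
  writeLines(c(header, sprintf("%.17g", as.numeric(x))), path)
  invisible(path)
}

#' Write a sparsity profile as CSV
#'
#' Layout mirrors the printed comparison tables: one row per threshold
#' (first column `c`), one column per basis (FFT, DCT, DST, DHT, W).
#'
#' @param profile A [sparsity_profile()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  if (!inherits(profile, "sparsity_profile") || nrow(profile) == 0) {
    cspa_stop("`profile` must be a non-empty sparsity_profile", "cspa_io_error")
  }
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a sparsity profile written by [write_profile()]
#'
#' @param path CSV path.
#' @return A `sparsity_profile` data frame.
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(df, class = c("sparsity_profile", "data.frame"),
            signal_label = "read", mode = NA_character_,
            N = NA_integer_)
}

#' Write / read a real matrix as whitespace-delimited text
#'
#' One row per line; `#` header comments carry provenance (ensemble, seed)
#' for measurement matrices.  Complex matrices (the Fourier synthesis
#' matrix) are not representable here; store those with `saveRDS()`.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @param metadata Named list of header comments.
#' @export
write_matrix_txt <- function(m, path, metadata = NULL) {
  if (!is.matrix(m) || !is.numeric(m)) {
    cspa_stop("`m` must be a real numeric matrix", "cspa_io_error")
  }
  header <- character(0)
  if (is.null(metadata) && inherits(m, "measurement_matrix")) {
    metadata <- list(ensemble = attr(m, "ensemble"), seed = attr(m, "seed"))
  }
  if (length(metadata)) {
    header <- sprintf("# %s: %s", names(metadata),
                      vapply(metadata, function(v) paste(format(v), collapse = " "),
                             character(1)))
  }
  body <- apply(unclass(m), 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  if (!file.exists(path)) {
    cspa_stop(sprintf("input file '%s' does not exist", path), "cspa_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  stripped <- stripped[nzchar(stripped)]
  if (!length(stripped)) {
    cspa_stop(sprintf("'%s' contains no matrix rows", path), "cspa_empty_input")
  }
  rows <- lapply(strsplit(stripped, "[ \t,]+"), as.numeric)
  if (any(vapply(rows, function(r) any(is.na(r)), logical(1)))) {
    cspa_stop(sprintf("malformed numeric row in '%s'", path), "cspa_parse_error")
  }
  do.call(rbind, rows)
}
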