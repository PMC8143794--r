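# File formats: trial tables as TSV with the canonical column set, epochs in a
# self-describing plain-text format (JSON header in '#' comment lines followed
# by a TSV body). TSV uses '.' decimals throughout to avoid locale ambiguity.

trial_table_columns <- function() {
  c(
    "session_id", "block", "trial_index", "phase", "as_type", "ts_context",
    "ts_direction", "ts_colour", "ts_coherence_pct", "as_response",
    "ts_response", "ts_correct", "ts_rt_ms"
  )
}

validate_trial_table <- function(trials) {
  missing_col <- setdiff(trial_table_columns(), names(trials))
  if (length(missing_col)) {
    stop("missing required column(s): ", paste(missing_col, collapse = ", "),
      call. = FALSE)
  }
  checks <- list(
    phase = c("screening", "meg_pre", "train_1d", "train_2d", "train_full", "meg_post"),
    as_type = as_types(),
    ts_context = c("colour", "motion"),
    ts_direction = c("left", "right"),
    ts_colour = c("green", "red"),
    as_response = c("index", "middle")
  )
  for (col in names(checks)) {
    bad <- which(!is.na(trials[[col]]) & !trials[[col]] %in% checks[[col]])
    if (length(bad)) {
      stop(sprintf("invalid value '%s' in column '%s' at row %d",
        trials[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
  }
  bad <- which(!is.na(trials$ts_response) &
    !trials$ts_response %in% c("index", "middle"))
  if (length(bad)) {
    stop(sprintf("invalid value in column 'ts_response' at row %d", bad[1]),
      call. = FALSE)
  }
  bad <- which(!is.na(trials$ts_coherence_pct) &
    !trials$ts_coherence_pct %in% c(12.8, 25.6, 70))
  if (length(bad)) {
    stop(sprintf(
      "invalid ts_coherence_pct %g at row %d (must be 12.8, 25.6 or 70)",
      trials$ts_coherence_pct[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(trials)
}

#' Read and write trial tables
#'
#' Trial tables are tab-separated with a header row, UTF-8 and '.' decimal
#' separator, with exactly the columns of the trial record (unknown extra
#' columns are preserved). Reading validates all enumerated columns and the
#' coherence levels and reports the offending column/row.
#'
#' @param path File path.
#' @return `read_trial_table()` returns a validated tibble.
#' @export
read_trial_table <- function(path) {
  trials <- readr::read_tsv(
    path,
    col_types = readr::cols(
      block = readr::col_integer(),
      trial_index = readr::col_integer(),
      ts_coherence_pct = readr::col_double(),
      ts_correct = readr::col_integer(),
      ts_rt_ms = readr::col_double(),
      .default = readr::col_character()
    ),
    comment = "#", progress = FALSE
  )
  validate_trial_table(trials)
  trials
}

#' @rdname read_trial_table
#' @param trials Trial tibble to write.
#' @param comment Optional header comment lines (written prefixed with `# `).
#' @export
write_trial_table <- function(trials, path, comment = NULL) {
  validate_trial_table(trials)
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(trials, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(trials, path, progress = FALSE)
  }
  invisible(path)
}

#' Read and write epoch files
#'
#' Epochs are stored in a self-describing text format: comment lines starting
#' with `#` carry a JSON header (`time_ms`, `sampling_rate_hz`, `session_id`,
#' dimensions, optional ground truth), followed by a TSV body with one row per
#' trial (2-D) or per trial x parcel (3-D, with explicit `trial` and `parcel`
#' index columns) and one column per sample. Values are written with 17
#' significant digits so a round trip is bit-identical.
#'
#' @param path File path.
#' @return `read_epochs()` returns a `source_epochs` object.
#' @export
read_epochs <- function(path) {
  lines <- readLines(path, n = 50)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr_json <- sub("^#", "", hdr_lines[startsWith(hdr_lines, "#json:")])
  hdr_json <- sub("^json:", "", hdr_json)
  if (!length(hdr_json)) stop("no epoch header found in ", path, call. = FALSE)
  hdr <- jsonlite::fromJSON(paste(hdr_json, collapse = ""))
  # time axis stored as %.17g strings so a round trip is bit-identical
  hdr$time_ms <- as.numeric(hdr$time_ms)
  body <- utils::read.table(path,
    header = TRUE, sep = "\t", comment.char = "#",
    colClasses = "numeric", check.names = FALSE
  )
  time_ms <- as.numeric(hdr$time_ms)
  spacing <- diff(time_ms)
  if (any(spacing <= 0) || max(abs(spacing - spacing[1])) > 1e-6) {
    stop("time axis must be strictly increasing with uniform spacing",
      call. = FALSE)
  }
  dims <- as.integer(hdr$dims)
  if (length(dims) == 3) {
    stopifnot(all(c("trial", "parcel") %in% names(body)))
    vals <- as.matrix(body[, setdiff(names(body), c("trial", "parcel"))])
    if (ncol(vals) != length(time_ms) || nrow(vals) != dims[1] * dims[2]) {
      stop("epoch data shape does not match header/time axis", call. = FALSE)
    }
    dat <- array(0, dim = dims)
    for (r in seq_len(nrow(vals))) {
      dat[body$trial[r], body$parcel[r], ] <- vals[r, ]
    }
  } else {
    vals <- as.matrix(body[, setdiff(names(body), "trial")])
    if (ncol(vals) != length(time_ms) || nrow(vals) != dims[1]) {
      stop("epoch data shape does not match header/time axis", call. = FALSE)
    }
    dat <- vals
    dimnames(dat) <- NULL
  }
  new_source_epochs(
    dat, time_ms, hdr$sampling_rate_hz, hdr$session_id,
    ground_truth = hdr$ground_truth
  )
}

#' @rdname read_epochs
#' @param epochs A `source_epochs` object to write.
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  spacing <- diff(epochs$time_ms)
  if (any(spacing <= 0) || max(abs(spacing - spacing[1])) > 1e-6) {
    stop("time axis must be strictly increasing with uniform spacing",
      call. = FALSE)
  }
  if (utils::tail(d, 1) != length(epochs$time_ms)) {
    stop("epoch data shape does not match the time axis", call. = FALSE)
  }
  hdr <- list(
    format = "choicetrace-epochs-v1",
    dims = d,
    time_ms = sprintf("%.17g", epochs$time_ms),
    sampling_rate_hz = epochs$sampling_rate_hz,
    session_id = epochs$session_id
  )
  if (!is.null(epochs$ground_truth)) {
    hdr$ground_truth <- epochs$ground_truth
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#json:", jsonlite::toJSON(hdr,
    auto_unbox = TRUE, digits = NA, null = "null"
  )), con)
  fmt <- function(x) sprintf("%.17g", x)
  sample_names <- paste0("s", seq_along(epochs$time_ms))
  if (length(d) == 3) {
    writeLines(paste(c("trial", "parcel", sample_names), collapse = "\t"), con)
    for (i in seq_len(d[1])) {
      for (p in seq_len(d[2])) {
        writeLines(
          paste(c(i, p, fmt(epochs$data[i, p, ])), collapse = "\t"), con
        )
      }
    }
  } else {
    writeLines(paste(c("trial", sample_names), collapse = "\t"), con)
    for (i in seq_len(d[1])) {
      writeLines(paste(c(i, fmt(epochs$data[i, ])), collapse = "\t"), con)
    }
  }
  invisible(path)
}
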