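#' Read a session from disk
#'
#' A session on disk is a pair of files: a UTF-8 tab-delimited trial table
#' (one row per trial, named-column header) and a sidecar JSON header carrying
#' the session metadata (`neuron_id`, `area`, `monkey_id`, `stim_dur_ms`,
#' `preferred_sign_fixation`, optional `slant_ladder_deg`). The header path is
#' the table path with its extension replaced by `.json` unless given
#' explicitly. Spike times, when present, are stored in the table as a
#' comma-separated string per row.
#'
#' @param path Path to the trial table (`.tsv`).
#' @param header_path Optional explicit path to the JSON header.
#' @return A validated [session()].
#' @export
read_session <- function(path, header_path = NULL) {
  if (!file.exists(path)) abort(paste0("I/O error: no such file: ", path))
  header_path <- header_path %||% sub("\\.[^.]+$", ".json", path)
  if (!file.exists(header_path)) {
    abort(paste0("I/O error: missing session header: ", header_path))
  }
  hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("spike_times_ms" %in% names(tr)) {
    tr$spike_times_ms <- lapply(as.character(tr$spike_times_ms), function(s) {
      if (is.na(s) || s == "") numeric(0)
      else as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  session(
    trials = tr,
    neuron_id = hdr$neuron_id %||% "unknown",
    area = hdr$area %||% "CIP",
    monkey_id = hdr$monkey_id %||% "unknown",
    stim_dur_ms = hdr$stim_dur_ms %||% 1000L,
    preferred_sign_fixation = hdr$preferred_sign_fixation %||% "unknown",
    slant_ladder_deg = hdr$slant_ladder_deg
  )
}

#' Write a session to disk
#'
#' Inverse of [read_session()]: writes the trial table as TSV and the metadata
#' as a JSON sidecar, so that `read_session(write_session(x, p))` returns an
#' identical session.
#'
#' @param x A `slant_session`.
#' @param path Output path for the trial table (`.tsv`).
#' @param header_path Optional explicit path for the JSON header.
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path, header_path = NULL) {
  stopifnot(inherits(x, "slant_session"))
  header_path <- header_path %||% sub("\\.[^.]+$", ".json", path)
  tr <- x$trials
  if ("spike_times_ms" %in% names(tr)) {
    tr$spike_times_ms <- vapply(tr$spike_times_ms, function(st) {
      if (is.null(st) || length(st) == 0) "" else paste(format(st, digits = 12, trim = TRUE, scientific = FALSE), collapse = ",")
    }, character(1))
  }
  readr::write_tsv(tr, path, progress = FALSE)
  hdr <- list(
    neuron_id = x$neuron_id, area = x$area, monkey_id = x$monkey_id,
    stim_dur_ms = x$stim_dur_ms,
    preferred_sign_fixation = x$preferred_sign_fixation
  )
  if (!is.null(x$slant_ladder_deg)) hdr$slant_ladder_deg <- x$slant_ladder_deg
  jsonlite::write_json(hdr, header_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Scalar-valued results (fits, choice-probability summaries, partial
#' correlations) are written as JSON; per-bin or per-trial series (time
#' courses, per-slant tables) are written as TSV next to the JSON. The seed
#' and configuration recorded on the object, if any, are embedded so every
#' output is self-describing.
#'
#' @param x A result object returned by the analysis functions, or any named
#'   list/tibble.
#' @param path Output path; `.json` for scalar results, `.tsv` for tables.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(paste0("I/O error: no such directory: ", dir))
  if (is.data.frame(x)) {
    readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
    return(invisible(path))
  }
  payload <- result_payload(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

# strip function/environment slots, keep tables as-is
result_payload <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    out <- lapply(x, result_payload)
    attrs <- attributes(x)
    out$.class <- paste(class(x), collapse = "/")
    out
  } else x
}

#' Read a scalar result written by [write_results()]
#'
#' @param path Path to a `.json` result file.
#' @return A named list.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("I/O error: no such file: ", path))
  if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
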