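#' Read and write paired-comparison trial tables
#'
#' Trials are stored as UTF-8 CSV with a header row and columns
#' `participant_id`, `group`, `repetition`, `first_db`, `second_db`,
#' `choice` (`"first"` or `"second"`). Reading validates the forced-choice
#' contract and reports the first offending file line; writing then reading
#' reproduces the records exactly.
#'
#' @param path File path.
#' @param extra_cols `"preserve"` (default) keeps unknown columns,
#'   `"drop"` discards them.
#' @return `read_trials()` returns a tibble of trials; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path, extra_cols = c("preserve", "drop")) {
  extra_cols <- match.arg(extra_cols)
  mandatory <- c("participant_id", "group", "repetition", "first_db",
                 "second_db", "choice")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(mandatory, names(x))
  if (length(missing)) {
    abort(paste0("Trials file is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "prefnr_parse_error")
  }
  if (extra_cols == "drop") x <- x[mandatory]
  # header is file line 1, so data row i sits on file line i + 1
  fail <- function(rows, what) {
    abort(paste0(what, " (file line ", rows[1] + 1L, ")"),
          class = "prefnr_parse_error")
  }
  for (col in c("first_db", "second_db")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) fail(bad, paste0("Non-numeric `", col, "` value"))
    x[[col]] <- v
  }
  rep_v <- suppressWarnings(as.integer(x$repetition))
  bad <- which(is.na(rep_v) | rep_v < 1)
  if (length(bad)) fail(bad, "`repetition` must be a positive integer")
  x$repetition <- rep_v
  bad <- which(!x$choice %in% c("first", "second"))
  if (length(bad)) fail(bad, '`choice` must be "first" or "second"')
  bad <- which(x$first_db == x$second_db)
  if (length(bad)) fail(bad, "`first_db` equals `second_db`")
  x
}

#' @rdname read_trials
#' @param trials Tibble of trials as produced by the simulators or
#'   [read_trials()].
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Read and write participant metadata
#'
#' Metadata CSV columns: `participant_id`, `group` (NH, HI-mild or
#' HI-moderate), `pta_better_db_hl` (pure-tone average at 1, 2, 4 kHz of the
#' better ear, dB HL), `age_years`, `srt_db` (speech reception threshold for
#' CVC words in quiet; may be blank when not measured).
#'
#' @param path File path.
#' @return `read_participants()` returns a tibble; `write_participants()`
#'   returns `path` invisibly.
#' @export
read_participants <- function(path) {
  mandatory <- c("participant_id", "group", "pta_better_db_hl", "age_years",
                 "srt_db")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         participant_id = readr::col_character(),
                         group = readr::col_character(),
                         .default = readr::col_double()
                       ))
  missing <- setdiff(mandatory, names(x))
  if (length(missing)) {
    abort(paste0("Metadata file is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "prefnr_parse_error")
  }
  x
}

#' @rdname read_participants
#' @param meta Tibble of participant metadata.
#' @export
write_participants <- function(meta, path) {
  readr::write_csv(meta, path, progress = FALSE)
  invisible(path)
}
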