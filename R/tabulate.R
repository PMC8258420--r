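# Sequence tabulation: flatten DICOM-header records into SeqInfo rows that
# heuristic rules branch on.

SEQINFO_COLS <- c("series_id", "subject_label", "session_label", "series_number",
                  "series_description", "protocol_name", "sequence_name",
                  "image_type", "repetition_time", "echo_time",
                  "dim1", "dim2", "dim3", "dim4", "series_files")

# fields forming the distinct-parameter key for unique-mode tabulation
SEQ_KEY_COLS <- c("series_description", "protocol_name", "sequence_name",
                  "image_type", "repetition_time", "echo_time",
                  "dim1", "dim2", "dim3", "dim4")

empty_seqinfo <- function() {
  tibble(
    series_id = character(), subject_label = character(), session_label = character(),
    series_number = integer(), series_description = character(),
    protocol_name = character(), sequence_name = character(),
    image_type = character(), repetition_time = double(), echo_time = double(),
    dim1 = integer(), dim2 = integer(), dim3 = integer(), dim4 = integer(),
    series_files = integer()
  )
}

header_chr <- function(h, field) {
  v <- h[[field]]
  if (is.null(v)) NA_character_ else as.character(v)
}

header_num <- function(h, field) {
  v <- h[[field]]
  if (is.null(v)) NA_real_ else as.numeric(v)
}

header_int <- function(h, field) {
  v <- h[[field]]
  if (is.null(v)) NA_integer_ else as.integer(v)
}

#' Extract SeqInfo rows from one session
#'
#' Produces one row per acquisition that holds a DICOM-header record;
#' acquisitions without one are skipped with a warning. Repetition and echo
#' times are converted from the header's milliseconds to seconds; the
#' multi-valued `ImageType` header is flattened by joining with `"_"`.
#' `series_id` is `<subject>_<session>_<series_number>`, which makes heuristic
#' assignments reproducible across runs.
#'
#' @param session A `bc_session`, typically from [select_sessions()].
#' @param subject_label Label of the enclosing subject; defaults to the
#'   attribute attached by [select_sessions()].
#' @return A tibble of SeqInfo rows.
#' @export
extract_seqinfo <- function(session, subject_label = attr(session, "subject_label")) {
  if (is.null(subject_label)) abort("subject_label is required", class = "bc_usage_error")
  rows <- list()
  for (acq in session$acquisitions) {
    header <- NULL
    for (f in acq$files) {
      h <- f$info[[NS_DICOM]]
      if (!is.null(h)) { header <- h; break }
    }
    if (is.null(header)) {
      warn(sprintf("acquisition '%s' has no DICOM header record; skipped", acq$label))
      next
    }
    series_number <- header_int(header, "SeriesNumber")
    image_type <- header$ImageType
    image_type <- if (is.null(image_type)) NA_character_ else {
      paste(unlist(image_type), collapse = "_")
    }
    tr <- header_num(header, "RepetitionTime")
    te <- header_num(header, "EchoTime")
    rows[[length(rows) + 1]] <- tibble(
      series_id = sprintf("%s_%s_%d", subject_label, session$label, series_number),
      subject_label = subject_label,
      session_label = session$label,
      series_number = series_number,
      series_description = header_chr(header, "SeriesDescription"),
      protocol_name = header_chr(header, "ProtocolName"),
      sequence_name = header_chr(header, "SequenceName"),
      image_type = image_type,
      repetition_time = tr / 1000,   # DICOM headers carry milliseconds
      echo_time = te / 1000,
      dim1 = header_int(header, "Rows"),
      dim2 = header_int(header, "Columns"),
      dim3 = header_int(header, "Slices"),
      dim4 = header_int(header, "Volumes"),
      series_files = length(acq$files)
    )
  }
  if (length(rows) == 0) return(empty_seqinfo())
  out <- bind_rows(rows)
  check_unique(out$series_id, "series_id values in session")
  out
}

#' Tabulate DICOM-header sequence information across a project
#'
#' Compiles SeqInfo rows for every selected session into one table, giving an
#' overview of the scanning sequences collected. In unique mode the table is
#' reduced to one row per distinct combination of the sequence-parameter key
#' (description, protocol, sequence name, image type, TR, TE, and the four
#' dimensions), keeping the first-seen row — this is the view users consult
#' when writing a heuristic.
#'
#' @param project A `bc_project`.
#' @param subject_labels,session_labels Optional filters, as in
#'   [select_sessions()].
#' @param unique Collapse to distinct parameter combinations?
#' @return A SeqInfo tibble with the fixed column order.
#' @export
tabulate_project <- function(project, subject_labels = NULL, session_labels = NULL,
                             unique = FALSE) {
  sessions <- select_sessions(project, subject_labels, session_labels)
  tab <- if (length(sessions) == 0) empty_seqinfo() else {
    bind_rows(map(sessions, extract_seqinfo))
  }
  if (isTRUE(unique)) {
    tab <- distinct(tab, across(all_of(SEQ_KEY_COLS)), .keep_all = TRUE) |>
      select(all_of(SEQINFO_COLS))
  }
  tab
}

#' Write / read a SeqInfo table as TSV
#'
#' Tab-separated, header row first, one line per SeqInfo row; missing numeric
#' fields serialize as empty strings (not 0, which would fake parameter-key
#' collisions in unique mode). `read_seq_table()` restores the committed
#' column types so a written table round-trips identically.
#'
#' @param table A SeqInfo tibble.
#' @param path Output file.
#' @return `path`, invisibly (`write_seq_table`); the tibble
#'   (`read_seq_table`).
#' @export
write_seq_table <- function(table, path) {
  readr::write_tsv(table[, SEQINFO_COLS], path, na = "")
  invisible(path)
}

#' @rdname write_seq_table
#' @export
read_seq_table <- function(path) {
  readr::read_tsv(
    path, na = "",
    col_types = readr::cols(
      series_id = readr::col_character(), subject_label = readr::col_character(),
      session_label = readr::col_character(), series_number = readr::col_integer(),
      series_description = readr::col_character(), protocol_name = readr::col_character(),
      sequence_name = readr::col_character(), image_type = readr::col_character(),
      repetition_time = readr::col_double(), echo_time = readr::col_double(),
      dim1 = readr::col_integer(), dim2 = readr::col_integer(),
      dim3 = readr::col_integer(), dim4 = readr::col_integer(),
      series_files = readr::col_integer()
    )
  )
}
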