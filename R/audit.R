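# Project auditor: sequence inventory, BIDS curation state, pipeline-run
# outcomes, and per-subject completeness against a template subject, rendered
# as a static HTML report plus CSV tables.

# Sequence identity is SeriesDescription string equality throughout.
acquisition_sequence <- function(acq) {
  for (f in acq$files) {
    h <- f$info[[NS_DICOM]]
    if (!is.null(h)) return(header_chr(h, "SeriesDescription"))
  }
  NA_character_
}

# long tibble: one row per NIfTI file with its sequence label and BIDS key
project_file_inventory <- function(project) {
  rows <- list()
  for (sub in project$subjects) {
    for (ses in sub$sessions) {
      for (acq in ses$acquisitions) {
        seq_label <- acquisition_sequence(acq)
        for (f in acq$files) {
          if (f$kind != "nifti") next
          rows[[length(rows) + 1]] <- tibble(
            subject_label = sub$label, session_label = ses$label,
            sequence = seq_label,
            bids_template = f$info[[NS_BIDS]]$template_key %||% NA_character_
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(subject_label = character(), session_label = character(),
                  sequence = character(), bids_template = character()))
  }
  bind_rows(rows)
}

# long tibble of analysis records with owning subject (when subject-scoped)
project_gear_inventory <- function(project) {
  rows <- list()
  push <- function(a, subject_label) {
    rows[[length(rows) + 1]] <<- tibble(
      subject_label = subject_label, gear_name = a$gear_name,
      gear_version = a$gear_version, status = a$status,
      finished = a$finished, runtime_seconds = a$runtime_seconds
    )
  }
  for (a in project$analyses) push(a, NA_character_)
  for (sub in project$subjects) {
    for (a in sub$analyses) push(a, sub$label)
    for (ses in sub$sessions) {
      for (a in ses$analyses) push(a, sub$label)
      for (acq in ses$acquisitions) for (a in acq$analyses) push(a, sub$label)
    }
  }
  if (length(rows) == 0) {
    return(tibble(subject_label = character(), gear_name = character(),
                  gear_version = character(), status = character(),
                  finished = character(), runtime_seconds = double()))
  }
  bind_rows(rows)
}

#' Enumerate collected sequences
#'
#' Groups NIfTI files by their acquisition's sequence label
#' (`SeriesDescription`) and counts files per sequence across the whole
#' project.
#'
#' @param project A `bc_project`.
#' @return A tibble (`sequence`, `files`), sorted by sequence.
#' @export
audit_sequences <- function(project) {
  inv <- project_file_inventory(project)
  inv |> count(.data$sequence, name = "files") |> arrange(.data$sequence)
}

#' Enumerate BIDS curation state per sequence
#'
#' For each (sequence label, BIDS naming-template key) pair, counts the
#' distinct subjects owning a file so named. Uncurated sequences appear with
#' an empty (`NA`) template.
#'
#' @param project A `bc_project`.
#' @return A tibble (`sequence`, `bids_template`, `subjects`).
#' @export
audit_bids <- function(project) {
  inv <- project_file_inventory(project)
  inv |>
    group_by(.data$sequence, .data$bids_template) |>
    summarise(subjects = n_distinct(.data$subject_label), .groups = "drop") |>
    arrange(.data$sequence, .data$bids_template)
}

#' Enumerate pipeline ("gear") runs and their outcomes
#'
#' Per gear name and version: total recorded runs, the percent of subjects
#' whose latest run of that gear completed (rounded to the nearest integer),
#' the complementary failed percent, the count of subjects with a complete
#' latest run, and the collected runtimes. Gears with zero runs are absent.
#'
#' @param project A `bc_project`.
#' @return A tibble (`gear_name`, `gear_version`, `total_runs`,
#'   `percent_complete`, `percent_failed`, `complete_subjects`,
#'   `runtimes` list-column).
#' @export
audit_gears <- function(project) {
  inv <- project_gear_inventory(project) |> filter(!is.na(.data$subject_label))
  if (nrow(inv) == 0) {
    return(tibble(gear_name = character(), gear_version = character(),
                  total_runs = integer(), percent_complete = double(),
                  percent_failed = double(), complete_subjects = integer(),
                  runtimes = list()))
  }
  latest <- inv |>
    group_by(.data$gear_name, .data$gear_version, .data$subject_label) |>
    slice_max(.data$finished, n = 1, with_ties = FALSE) |>
    ungroup()
  inv |>
    group_by(.data$gear_name, .data$gear_version) |>
    summarise(total_runs = n(), runtimes = list(.data$runtime_seconds),
              .groups = "drop") |>
    left_join(
      latest |>
        group_by(.data$gear_name, .data$gear_version) |>
        summarise(n_subjects = n_distinct(.data$subject_label),
                  complete_subjects = sum(.data$status == "complete"),
                  .groups = "drop"),
      by = c("gear_name", "gear_version")
    ) |>
    mutate(percent_complete = round(100 * .data$complete_subjects / .data$n_subjects),
           percent_failed = 100 - .data$percent_complete) |>
    select("gear_name", "gear_version", "total_runs", "percent_complete",
           "percent_failed", "complete_subjects", runtimes = "runtimes") |>
    arrange(.data$gear_name, .data$gear_version)
}

#' Completeness of every subject against a template subject
#'
#' The template subject is an exemplar assumed to have complete data and
#' analyses; its sequences, BIDS templates and (gear, version) pairs define
#' the columns of three matrices. Every other subject is a row; a cell is
#' `"complete"` when the subject has at least as many matching items as the
#' template (for gears: a run of that gear whose version matches the
#' template's exactly, with complete status), `"incomplete"` otherwise.
#'
#' @param project A `bc_project`.
#' @param template_subject Label of the template subject.
#' @return A list of three wide tibbles (`sequences`, `bids`, `gears`), each
#'   with a `subject_label` column followed by one column per template item.
#' @export
completeness <- function(project, template_subject) {
  labels <- map_chr(project$subjects, "label")
  if (!template_subject %in% labels) {
    abort(sprintf("template subject '%s' not in project", template_subject),
          class = "bc_not_found_error")
  }
  others <- setdiff(labels, template_subject)
  files <- project_file_inventory(project)
  gears <- project_gear_inventory(project) |> filter(!is.na(.data$subject_label))

  cell <- function(ok) ifelse(ok, "complete", "incomplete")

  count_matrix <- function(tbl, column) {
    tmpl <- tbl |>
      filter(.data$subject_label == template_subject, !is.na(.data[[column]])) |>
      count(.data[[column]], name = "needed")
    out <- tibble(subject_label = others)
    for (i in seq_len(nrow(tmpl))) {
      item <- tmpl[[column]][[i]]
      needed <- tmpl$needed[[i]]
      have <- tbl |>
        filter(.data[[column]] == item, !is.na(.data[[column]])) |>
        count(.data$subject_label, name = "have")
      got <- have$have[match(others, have$subject_label)]
      got[is.na(got)] <- 0L
      out[[item]] <- cell(got >= needed)
    }
    out
  }

  tmpl_gears <- gears |>
    filter(.data$subject_label == template_subject) |>
    distinct(.data$gear_name, .data$gear_version)
  gear_out <- tibble(subject_label = others)
  for (i in seq_len(nrow(tmpl_gears))) {
    gname <- tmpl_gears$gear_name[[i]]
    gver <- tmpl_gears$gear_version[[i]]
    ok_subjects <- gears |>
      filter(.data$gear_name == gname, .data$gear_version == gver,
             .data$status == "complete") |>
      pull(.data$subject_label) |>
      unique()
    gear_out[[sprintf("%s %s", gname, gver)]] <- cell(others %in% ok_subjects)
  }

  list(sequences = count_matrix(files, "sequence"),
       bids = count_matrix(files |> filter(!is.na(.data$bids_template)), "bids_template"),
       gears = gear_out)
}

#' Audit a whole project
#'
#' Bundles the three overview tables ([audit_sequences()], [audit_bids()],
#' [audit_gears()]) and, when a template subject is named, the three
#' [completeness()] matrices. The audit is read-only on the store.
#'
#' @param project A `bc_project`.
#' @param template_subject Optional label of the exemplar subject.
#' @return A `bc_audit` bundle.
#' @export
audit_project <- function(project, template_subject = NULL) {
  structure(
    list(
      sequence_table = audit_sequences(project),
      bids_table = audit_bids(project),
      gear_table = audit_gears(project),
      completeness = if (!is.null(template_subject)) {
        completeness(project, template_subject)
      },
      template_subject = template_subject,
      project_label = project$label
    ),
    class = "bc_audit"
  )
}

#' @export
print.bc_audit <- function(x, ...) {
  cat(sprintf("<project audit> '%s': %d sequence(s), %d gear(s)%s\n",
              x$project_label, nrow(x$sequence_table), nrow(x$gear_table),
              if (is.null(x$completeness)) "" else
                sprintf(", completeness vs '%s'", x$template_subject)))
  invisible(x)
}

#' @rdname tidy.bc_validation
#' @export
tidy.bc_audit <- function(x, ...) {
  x$sequence_table
}

#' @rdname tidy.bc_validation
#' @export
glance.bc_audit <- function(x, ...) {
  tibble(n_sequences = nrow(x$sequence_table),
         n_files = sum(x$sequence_table$files),
         n_bids_templates = sum(!is.na(x$bids_table$bids_template)),
         n_gears = nrow(x$gear_table),
         has_completeness = !is.null(x$completeness))
}

## ---- plots ------------------------------------------------------------------

#' Audit figures
#'
#' `plot_sequence_counts()` is the sequence-enumeration bar chart (files per
#' sequence); `plot_gear_outcomes()` shows completed versus failed percent
#' per gear. `autoplot()` on a `bc_audit` returns the sequence chart.
#'
#' @param bundle A `bc_audit`.
#' @return A ggplot object.
#' @export
plot_sequence_counts <- function(bundle) {
  ggplot2::ggplot(bundle$sequence_table,
                  ggplot2::aes(x = stats::reorder(.data$sequence, .data$files),
                               y = .data$files)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Files", title = "Files per collected sequence") +
    ggplot2::theme_minimal()
}

#' @rdname plot_sequence_counts
#' @export
plot_gear_outcomes <- function(bundle) {
  long <- bundle$gear_table |>
    select("gear_name", "percent_complete", "percent_failed") |>
    tidyr::pivot_longer(c("percent_complete", "percent_failed"),
                        names_to = "outcome", values_to = "percent") |>
    mutate(outcome = sub("^percent_", "", .data$outcome))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gear_name, y = .data$percent,
                                     fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(complete = "#31a354", failed = "#de2d26")) +
    ggplot2::labs(x = NULL, y = "Percent of subjects", fill = NULL,
                  title = "Gear run outcomes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.bc_audit <- function(object, ...) plot_sequence_counts(object)

#' @export
ggplot2::autoplot

## ---- report -----------------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(tbl) {
  if (nrow(tbl) == 0) return("<p><em>No rows.</em></p>")
  fmt <- function(v) {
    if (is.list(v)) map_chr(v, ~ paste(.x, collapse = "; "))
    else as.character(v)
  }
  cells <- map(tbl, fmt)
  head <- paste0("<tr>", paste0("<th>", html_escape(names(tbl)), "</th>",
                                collapse = ""), "</tr>")
  body <- map_chr(seq_len(nrow(tbl)), function(i) {
    paste0("<tr>", paste0("<td>",
                          html_escape(map_chr(cells, ~ .x[[i]] %||% "")),
                          "</td>", collapse = ""), "</tr>")
  })
  paste0("<table>", head, paste(body, collapse = "\n"), "</table>")
}

csv_ready <- function(tbl) {
  for (nm in names(tbl)) {
    if (is.list(tbl[[nm]])) tbl[[nm]] <- map_chr(tbl[[nm]], ~ paste(.x, collapse = ";"))
  }
  tbl
}

#' Render the audit report
#'
#' Writes one static, self-contained HTML report (overview and completeness
#' sections) plus one CSV per table: `sequences.csv`, `bids.csv`,
#' `gears.csv`, and the three `completeness_*.csv` matrices (header-only when
#' no template subject was audited). List-valued columns (gear runtimes) are
#' joined with `";"` in the CSVs.
#'
#' @param bundle A `bc_audit`.
#' @param out_dir Output directory (created if needed).
#' @return A tibble of written paths, invisibly.
#' @export
render_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    abort(sprintf("output dir '%s' is not writable", out_dir), class = "bc_io_error")
  }
  comp <- bundle$completeness %||% list(
    sequences = tibble(subject_label = character()),
    bids = tibble(subject_label = character()),
    gears = tibble(subject_label = character())
  )
  tables <- list(
    sequences = bundle$sequence_table,
    bids = bundle$bids_table,
    gears = bundle$gear_table,
    completeness_sequences = comp$sequences,
    completeness_bids = comp$bids,
    completeness_gears = comp$gears
  )
  written <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(csv_ready(tables[[nm]]), path, na = "")
    written <- c(written, path)
  }
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>Project audit: %s</title>", html_escape(bundle$project_label)),
    "<style>body{font-family:sans-serif;margin:2em;}table{border-collapse:collapse;margin:1em 0;}",
    "td,th{border:1px solid #999;padding:4px 8px;}th{background:#eee;}</style></head><body>",
    sprintf("<h1>Project audit: %s</h1>", html_escape(bundle$project_label)),
    "<h2>Overview</h2>",
    "<h3>Sequences</h3>", html_table(tables$sequences),
    "<h3>BIDS curation</h3>", html_table(tables$bids),
    "<h3>Gear runs</h3>", html_table(csv_ready(tables$gears)),
    "<h2>Completeness</h2>",
    if (is.null(bundle$completeness)) {
      "<p><em>No template subject specified.</em></p>"
    } else {
      sprintf("<p>Template subject: <strong>%s</strong></p>",
              html_escape(bundle$template_subject))
    },
    "<h3>Sequences</h3>", html_table(comp$sequences),
    "<h3>BIDS</h3>", html_table(comp$bids),
    "<h3>Gears</h3>", html_table(comp$gears),
    "</body></html>"
  )
  report <- file.path(out_dir, "report.html")
  writeLines(html, report, useBytes = TRUE)
  written <- c(report, written)
  invisible(tibble(path = written))
}
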