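# Subset BIDS validation with stable rule codes:
#   R1 dataset_description.json present, parseable, with Name + BIDSVersion
#   R2 image filenames match the committed entity grammar
#   R3 sub-/ses- filename entities match the enclosing directories
#   R4 suffix consistent with its datatype folder
#   R5 every func image carries a task entity
#   R6 every fmap IntendedFor target resolves to an existing file
#   R7 subject/session directory labels are alphanumeric
#   R8 no duplicate paths
# All rule violations are errors; an unknown suffix (datatype folder "other")
# is the warning W1. The official BIDS Validator can be delegated to from the
# command line via --external-validator.

FILENAME_GRAMMAR <- paste0(
  "^sub-[A-Za-z0-9]+",
  "(_ses-[A-Za-z0-9]+)?",
  "(_task-[A-Za-z0-9]+)?",
  "(_acq-[A-Za-z0-9]+)?",
  "(_dir-[A-Za-z0-9]+)?",
  "(_run-[0-9]+)?",
  "_[A-Za-z0-9]+\\.nii\\.gz$"
)

issue_row <- function(code, severity, path, message) {
  tibble(code = code, severity = severity, path = path, message = message)
}

entity_value <- function(filename, entity) {
  m <- regmatches(filename, regexpr(sprintf("(?<=%s-)[A-Za-z0-9]+", entity),
                                    filename, perl = TRUE))
  if (length(m) == 0) NA_character_ else m
}

# Uniform view of a dataset: image paths, parsed sidecars, description record,
# and the complete path set — built either from an exported tree or from the
# in-store BIDS namespaces of a project.
dataset_view <- function(x) {
  if (inherits(x, "bc_project")) {
    images <- character(0)
    sidecars <- list()
    for (path in container_paths(x)) {
      node <- get_container(x, path)
      for (f in node$files) {
        bids <- f$info[[NS_BIDS]]
        if (is.null(bids$relative_path)) next
        if (f$kind == "nifti") {
          images <- c(images, bids$relative_path)
          sc <- sidecar_for(NULL, bids)
          if (length(sc$IntendedFor)) sidecars[[bids$relative_path]] <- sc
        }
      }
    }
    desc <- dataset_description(x)
    # attachments are the non-image files carrying a recorded BIDS path;
    # images enter all_paths unduplicated so R8 can catch collisions
    attachments <- setdiff(curated_relative_paths(x), images)
    list(images = images, sidecars = sidecars,
         description = desc, description_parse_error = NULL,
         all_paths = c(images, attachments,
                       if (!is.null(desc)) "dataset_description.json"))
  } else {
    root <- x
    if (!dir.exists(root)) {
      abort(sprintf("unreadable dataset root '%s'", root), class = "bc_io_error")
    }
    all_paths <- list.files(root, recursive = TRUE, full.names = FALSE)
    images <- all_paths[grepl("\\.nii\\.gz$", all_paths)]
    desc <- NULL
    desc_err <- NULL
    desc_path <- file.path(root, "dataset_description.json")
    if (file.exists(desc_path)) {
      desc <- tryCatch(jsonlite::fromJSON(desc_path, simplifyVector = FALSE),
                       error = function(e) { desc_err <<- conditionMessage(e); NULL })
    }
    sidecars <- list()
    for (img in images) {
      sc_path <- file.path(root, sub("\\.nii\\.gz$", ".json", img))
      if (file.exists(sc_path)) {
        sidecars[[img]] <- tryCatch(jsonlite::fromJSON(sc_path, simplifyVector = FALSE),
                                    error = function(e) NULL)
      }
    }
    list(images = images, sidecars = sidecars, description = desc,
         description_parse_error = desc_err, all_paths = all_paths)
  }
}

#' Validate a BIDS tree or a curated project
#'
#' Applies the committed rule subset (R1-R8, see the package vignette) either
#' to an exported directory tree or directly to the BIDS namespaces held in a
#' project store. Validation is pure: the same input always yields the same
#' issue table, sorted by code then path.
#'
#' @param x A dataset root directory, or a `bc_project`.
#' @return A `bc_validation`: list with `issues` (tibble of `code`,
#'   `severity`, `path`, `message`) and `valid` (`TRUE` iff no
#'   error-severity issues).
#' @export
validate_dataset <- function(x) {
  view <- dataset_view(x)
  issues <- list()
  add <- function(...) issues[[length(issues) + 1]] <<- issue_row(...)

  # R1: dataset description
  if (is.null(view$description)) {
    add("R1", "error", "dataset_description.json",
        if (is.null(view$description_parse_error)) "dataset_description.json is missing"
        else sprintf("dataset_description.json does not parse: %s",
                     view$description_parse_error))
  } else {
    absent <- setdiff(c("Name", "BIDSVersion"), names(view$description))
    if (length(absent)) {
      add("R1", "error", "dataset_description.json",
          sprintf("dataset_description.json lacks required field(s): %s",
                  paste(absent, collapse = ", ")))
    }
  }

  # R8: duplicate paths
  dups <- unique(view$all_paths[duplicated(view$all_paths)])
  for (d in dups) add("R8", "error", d, "duplicate path")

  for (img in view$images) {
    parts <- strsplit(img, "/", fixed = TRUE)[[1]]
    filename <- parts[[length(parts)]]

    if (!grepl(FILENAME_GRAMMAR, filename)) {
      add("R2", "error", img, "filename does not match the BIDS entity grammar")
      next
    }
    sub_ent <- entity_value(filename, "sub")
    ses_ent <- entity_value(filename, "ses")

    dir_sub <- if (length(parts) >= 2) sub("^sub-", "", parts[[1]]) else NA_character_
    dir_ses <- if (length(parts) >= 3 && grepl("^ses-", parts[[2]])) {
      sub("^ses-", "", parts[[2]])
    } else NA_character_
    if (!identical(sub_ent, dir_sub) ||
        (!is.na(ses_ent) || !is.na(dir_ses)) && !identical(ses_ent, dir_ses)) {
      add("R3", "error", img,
          "sub-/ses- entities do not match the enclosing directories")
    }
    if (!is.na(dir_sub) && !grepl("^[A-Za-z0-9]+$", dir_sub)) {
      add("R7", "error", img, sprintf("subject label '%s' is not alphanumeric", dir_sub))
    }
    if (!is.na(dir_ses) && !grepl("^[A-Za-z0-9]+$", dir_ses)) {
      add("R7", "error", img, sprintf("session label '%s' is not alphanumeric", dir_ses))
    }

    folder <- if (length(parts) >= 2) parts[[length(parts) - 1]] else NA_character_
    suffix <- sub("^.*_([A-Za-z0-9]+)\\.nii\\.gz$", "\\1", filename)
    expected <- unname(SUFFIX_FOLDERS[suffix])
    if (is.na(expected)) {
      add("W1", "warning", img,
          sprintf("suffix '%s' has no committed datatype folder", suffix))
    } else if (!identical(expected, folder)) {
      add("R4", "error", img,
          sprintf("suffix '%s' belongs in '%s/', found in '%s/'", suffix, expected,
                  folder %||% "?"))
    }
    if (identical(folder, "func") && is.na(entity_value(filename, "task"))) {
      add("R5", "error", img, "functional image lacks a task entity")
    }

    sc <- view$sidecars[[img]]
    if (identical(expected, "fmap") && length(sc$IntendedFor)) {
      for (target in unlist(sc$IntendedFor)) {
        resolved <- paste0("sub-", sub_ent, "/", target)
        if (!resolved %in% view$all_paths) {
          add("R6", "error", img,
              sprintf("IntendedFor target '%s' does not resolve to an existing file",
                      target))
        }
      }
    }
  }

  issues_tbl <- if (length(issues)) bind_rows(issues) else
    tibble(code = character(), severity = character(), path = character(),
           message = character())
  issues_tbl <- arrange(issues_tbl, .data$code, .data$path, .data$message)
  structure(list(issues = issues_tbl,
                 valid = !any(issues_tbl$severity == "error")),
            class = "bc_validation")
}

#' Tabulate validation issues by rule code
#'
#' @param result A `bc_validation` from [validate_dataset()].
#' @return A tibble with one row per distinct code: `code`, `severity`,
#'   `count`, `example_path`. Counts sum to the total number of issues.
#' @export
tabulate_validation <- function(result) {
  if (nrow(result$issues) == 0) {
    return(tibble(code = character(), severity = character(),
                  count = integer(), example_path = character()))
  }
  result$issues |>
    group_by(.data$code, .data$severity) |>
    summarise(count = n(), example_path = .data$path[[1]], .groups = "drop") |>
    arrange(.data$code)
}

#' @export
print.bc_validation <- function(x, ...) {
  mark <- if (x$valid) "PASS" else "FAIL"
  cat(sprintf("<BIDS validation> %s: %d error(s), %d warning(s)\n", mark,
              sum(x$issues$severity == "error"), sum(x$issues$severity == "warning")))
  if (nrow(x$issues)) print(tabulate_validation(x))
  invisible(x)
}

#' Broom-style accessors for validation results
#'
#' `tidy()` returns the issue table (one row per issue); `glance()` a
#' one-row summary with the binary validation status.
#'
#' @param x A `bc_validation`.
#' @param ... Unused.
#' @export
tidy.bc_validation <- function(x, ...) x$issues

#' @rdname tidy.bc_validation
#' @export
glance.bc_validation <- function(x, ...) {
  tibble(valid = x$valid,
         n_errors = sum(x$issues$severity == "error"),
         n_warnings = sum(x$issues$severity == "warning"),
         n_issues = nrow(x$issues))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
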