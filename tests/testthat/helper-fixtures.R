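# Fixture helpers. The preset stores are generated once per test run and
# copied for tests that mutate them; copies are byte-identical to the cache.

fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(which = c("overview", "completeness")) {
  which <- match.arg(which)
  if (is.null(fixture_cache[[which]])) {
    root <- file.path(tempdir(), paste0("cache-", which))
    fixture_cache[[which]] <- switch(which,
      overview = fixture_overview(root),
      completeness = fixture_completeness(root)
    )
  }
  fixture_cache[[which]]
}

# fresh, mutable copy of a cached preset store
fresh_fixture <- function(which = "overview") {
  src <- project_root(cached_fixture(which))
  dest <- tempfile(paste0(which, "-"))
  dir.create(dest)
  file.copy(list.files(src, full.names = TRUE), dest, recursive = TRUE)
  load_project(dest)
}

# tiny handmade project: 2 subjects x 1 session x 2 acquisitions
tiny_project <- function(root = tempfile("tiny-")) {
  generate_project(
    fixture_config(
      n_subjects = 2, label_scheme = "numeric", sessions_per_subject = 1,
      sequence_menu = list(
        sequence_entry("anat_T1w", 1, 2400, 2.2, c(256, 256, 176, 1)),
        sequence_entry("func_task-rest_bold", 1, 800, 30, c(64, 64, 44, 10))
      ),
      seed = 7
    ),
    root = root, label = "tiny"
  )
}

demo_spec <- function() load_heuristic(demo_heuristic_path())

write_heuristic <- function(lines) {
  path <- tempfile(fileext = ".R")
  writeLines(lines, path)
  path
}

# strip reader metadata (col spec etc.) before comparing tables
plain_df <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}

get_container_pub <- function(project, path) {
  getFromNamespace("get_container", "bidscurator")(project, path)
}

subject_labels_of <- function(project) {
  vapply(project$subjects, function(s) s$label, character(1))
}

# independent oracle: exhaustively walk the hierarchy counting NIfTI files
walk_count_nifti <- function(project) {
  n <- 0L
  for (sub in project$subjects) for (ses in sub$sessions) {
    for (acq in ses$acquisitions) for (f in acq$files) {
      if (f$kind == "nifti") n <- n + 1L
    }
  }
  n
}

# independent oracle: relative BIDS paths recorded anywhere in the metadata
walk_bids_paths <- function(project) {
  out <- character(0)
  rec <- function(node) {
    for (f in node$files) {
      rp <- f$info[["BIDS"]]$relative_path
      if (!is.null(rp)) out <<- c(out, rp)
    }
    for (field in intersect(c("subjects", "sessions", "acquisitions"), names(node))) {
      for (kid in node[[field]]) rec(kid)
    }
  }
  rec(project)
  out
}
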