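# Demonstration heuristic for the synthetic study fixtures.
#
# Top-level character scalars declare BIDS naming templates; classify()
# assigns series to template keys with Boolean rules over SeqInfo fields.

t1w <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"
rest_bold <- "sub-{SubjectLabel}_ses-{SessionLabel}_task-rest_bold.nii.gz"
b0map <- "sub-{SubjectLabel}_ses-{SessionLabel}_run-{item}_fieldmap.nii.gz"
dwi <- "sub-{SubjectLabel}_ses-{SessionLabel}_dwi.nii.gz"

classify <- function(seqinfo) {
  pick <- function(hit) seqinfo$series_id[!is.na(hit) & hit]
  list(
    t1w = pick(grepl("T1w", seqinfo$series_description, fixed = TRUE)),
    rest_bold = pick(grepl("task-rest", seqinfo$series_description, fixed = TRUE)),
    b0map = pick(grepl("B0map", seqinfo$series_description, fixed = TRUE)),
    dwi = pick(grepl("dwi", seqinfo$series_description, fixed = TRUE))
  )
}

# hardcoded sidecar fields for the fieldmap images
MetadataExtras <- list(
  b0map = list(Units = "Hz")
)

# point the fieldmaps at the sequence they correct
IntendedFor <- list(
  b0map = c("sub-{SubjectLabel}_ses-{SessionLabel}_task-rest_bold.nii.gz")
)

AttachToProject <- list(
  list(path = "README",
       content = "Synthetic demonstration study curated into BIDS.\n")
)
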