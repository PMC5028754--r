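#' Peptide-identification filter cascade
#'
#' The four-stage cascade turning raw MS identification lists into candidate
#' cleavage products: (1) keep peptides with a biotinylated neo-N-terminus;
#' (2) keep test peptides identified with confidence strictly over the test
#' threshold, control peptides over the control threshold; (3) remove test
#' peptides also present in the mock or inactive-enzyme controls; (4) remove
#' peptides already present in the unprocessed library run.
#'
#' @name pics_filter
NULL

as_peptide_ids <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("peptide", "nterm_biotin", "confidence") %in% names(x)))
  if (any(x$confidence < 0 | x$confidence > 100)) {
    stop("confidence values must lie in [0, 100]")
  }
  x
}

# Duplicate sequences within one run are collapsed to their
# highest-confidence instance (a biotinylated instance wins ties) before any
# filtering; identification lists are per-sequence evidence, not counts.
collapse_duplicates <- function(ids) {
  if (nrow(ids) < 2L) return(ids)
  o <- order(ids$peptide, -ids$confidence, !ids$nterm_biotin)
  keep <- o[!duplicated(ids$peptide[o])]
  ids[sort(keep), , drop = FALSE]
}

#' Keep peptides with a biotinylated N-terminus
#'
#' @param ids data.frame with columns `peptide`, `nterm_biotin`, `confidence`.
#' @return the rows with `nterm_biotin` true, order preserved.
#' @export
filter_biotinylated <- function(ids) {
  ids <- as_peptide_ids(ids)
  ids[ids$nterm_biotin, , drop = FALSE]
}

#' Keep peptides above a confidence threshold
#'
#' Retains identifications with confidence strictly greater than `threshold`
#' ("over" the threshold).
#'
#' @param ids peptide-identification data.frame.
#' @param threshold percentage in `[0, 100]`.
#' @export
apply_confidence_filter <- function(ids, threshold) {
  ids <- as_peptide_ids(ids)
  if (threshold < 0 || threshold > 100) stop("threshold must be in [0, 100]")
  ids[ids$confidence > threshold, , drop = FALSE]
}

#' Subtract control identifications from the test list
#'
#' Removes any test peptide whose sequence occurs in the inactive-enzyme or
#' mock control lists (exact sequence identity). Controls are expected to be
#' confidence-filtered at the control threshold already.
#'
#' @param test,inactive,mock peptide-identification data.frames.
#' @export
subtract_controls <- function(test, inactive, mock) {
  test <- as_peptide_ids(test)
  bad <- c(inactive$peptide, mock$peptide)
  test[!(test$peptide %in% bad), , drop = FALSE]
}

#' Remove peptides present in the unprocessed library
#'
#' @param test,library_run peptide-identification data.frames.
#' @export
remove_library_peptides <- function(test, library_run) {
  test <- as_peptide_ids(test)
  test[!(test$peptide %in% library_run$peptide), , drop = FALSE]
}

#' Run the full PICS filter cascade
#'
#' Applies, in order: duplicate collapse, biotin filter (all four runs),
#' confidence filters (test at `test_threshold`, controls and library run at
#' `control_threshold`), control subtraction, library removal. Stage counts
#' refer to the test list.
#'
#' @param runs a `pics_runs` list (fields `test`, `inactive`, `mock`,
#'   `library`), e.g. from [simulate_pics_runs()] or [read_runs_tsv()].
#' @param test_threshold confidence threshold (percent) for the test run;
#'   default 80.
#' @param control_threshold threshold for control and library runs; default 10.
#' @return list with `survivors` (peptide-identification data.frame) and
#'   `report` (named stage counts: `input`, `after_biotin`,
#'   `after_confidence`, `after_control_subtraction`, `after_library_removal`).
#' @export
run_cascade <- function(runs, test_threshold = 80, control_threshold = 10) {
  stopifnot(all(c("test", "inactive", "mock", "library") %in% names(runs)))
  test <- collapse_duplicates(as_peptide_ids(runs$test))
  inact <- collapse_duplicates(as_peptide_ids(runs$inactive))
  mock <- collapse_duplicates(as_peptide_ids(runs$mock))
  lib <- collapse_duplicates(as_peptide_ids(runs$library))

  n_input <- nrow(test)
  test <- filter_biotinylated(test)
  n_biotin <- nrow(test)
  test <- apply_confidence_filter(test, test_threshold)
  n_conf <- nrow(test)

  inact <- apply_confidence_filter(filter_biotinylated(inact), control_threshold)
  mock <- apply_confidence_filter(filter_biotinylated(mock), control_threshold)
  lib <- apply_confidence_filter(filter_biotinylated(lib), control_threshold)

  test <- subtract_controls(test, inact, mock)
  n_sub <- nrow(test)
  test <- remove_library_peptides(test, lib)
  n_lib <- nrow(test)
  rownames(test) <- NULL

  list(survivors = test,
       report = list(input = n_input, after_biotin = n_biotin,
                     after_confidence = n_conf,
                     after_control_subtraction = n_sub,
                     after_library_removal = n_lib))
}
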