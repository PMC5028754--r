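#' Run the full PICS analysis on one run set
#'
#' Convenience wrapper chaining the filter cascade, proteome back-mapping and
#' specificity-matrix construction.
#'
#' @param runs a `pics_runs` list.
#' @param proteome named character vector of protein sequences.
#' @param test_threshold,control_threshold cascade confidence thresholds
#'   (percent), defaults 80 and 10.
#' @param background optional 20-vector of background residue frequencies for
#'   [enrichment()].
#' @return list with `matrix` (a `specificity_matrix`), `windows`,
#'   `survivors`, `filter_report`, `mapping_report` and `status`
#'   (`"ok"` or `"no cleavage detected"` when zero windows remain).
#' @export
pics_pipeline <- function(runs, proteome, test_threshold = 80,
                          control_threshold = 10, background = NULL) {
  casc <- run_cascade(runs, test_threshold, control_threshold)
  mapped <- map_all(casc$survivors, proteome)
  mat <- build_matrix(mapped$windows, background = background)
  list(matrix = mat, windows = mapped$windows, survivors = casc$survivors,
       filter_report = casc$report, mapping_report = mapped$report,
       status = if (mat$n_windows == 0L) "no cleavage detected" else "ok")
}

#' Residue composition of a peptide library
#'
#' Frequency of each amino acid over all library peptides, usable as the
#' `background` of [build_matrix()].
#'
#' @param library data.frame from [digest_proteome()].
#' @return named 20-vector of frequencies summing to 1.
#' @export
library_background <- function(library) {
  res <- strsplit(paste(library$peptide, collapse = ""), "", fixed = TRUE)[[1]]
  tab <- table(factor(res, levels = AA_ALPHABET))
  stats::setNames(as.vector(tab / sum(tab)), AA_ALPHABET)
}
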