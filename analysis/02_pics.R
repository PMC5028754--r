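#!/usr/bin/env Rscript
# Stage 2: run the PICS analysis on both simulated screens.
# The positive screen should recover the planted hydrophobic-P1 preference;
# the null screen should end with zero cleavage windows, the qualitative
# outcome of the Ddi1 assay.

suppressPackageStartupMessages(library(picsitc))

proteome <- read_proteome_fasta("results/proteome.fasta")
lib <- digest_proteome(proteome, digest_rule())
bg <- library_background(lib)

for (screen in c("positive", "null")) {
  runs <- read_runs_tsv(sprintf("results/runs_%s.tsv", screen))
  res <- pics_pipeline(runs, proteome, test_threshold = 80,
                       control_threshold = 10, background = bg)
  message(sprintf("[%s] cascade: %s -> status: %s", screen,
                  paste(unlist(res$filter_report), collapse = " > "),
                  res$status))
  if (res$status == "ok") {
    message(sprintf("[%s] %d windows (%d ambiguous); top P1 residue: %s",
                    screen, res$matrix$n_windows,
                    res$mapping_report$n_ambiguous,
                    rownames(res$matrix$frequencies)[
                      which.max(res$matrix$frequencies[, "P1"])]))
    write_windows_tsv(res$windows,
                      sprintf("results/windows_%s.tsv", screen))
  }
  export_matrix(res$matrix, sprintf("results/specificity_%s.tsv", screen))
  write_fit_json(c(res$filter_report, res$mapping_report,
                   list(status = res$status)),
                 sprintf("results/pics_report_%s.json", screen))
}
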