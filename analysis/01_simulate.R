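#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses need.
#
# PICS side: a 100-protein random proteome, its tryptic (K/R, not before P)
# peptide library, and two screens against that library --
#   * "positive": an aspartyl-protease-like enzyme with a hydrophobic-P1
#     planted preference (the kind of profile the HIV-1 control produces),
#   * "null": the same enzyme with efficiency 0 (the catalytically dead
#     situation the Ddi1 screen reproduced at every pH).
# ITC side: noiseless forward-simulated titrations at the four printed
# injection protocols (9 uL x 30 into a 1.43 mL cell at 25 C).

suppressPackageStartupMessages(library(picsitc))
dir.create("results", showWarnings = FALSE)
seed <- 2026L

proteome <- generate_proteome(100, c(100, 300), seed = seed)
write_proteome_fasta(proteome, "results/proteome.fasta")
lib <- digest_proteome(proteome, digest_rule())
message(sprintf("proteome: %d proteins, library: %d tryptic peptides",
                length(proteome), nrow(lib)))

noise <- pics_noise(n_background = 400)
positive <- protease_spec(list(P1 = c(F = 1, L = 0.7, Y = 0.5),
                               P1p = c(P = 1, A = 0.6)),
                          efficiency = 0.8)
write_runs_tsv(simulate_pics_runs(lib, positive, noise, seed = seed),
               "results/runs_positive.tsv")
null_enzyme <- protease_spec(list(P1 = c(F = 1)), efficiency = 0)
write_runs_tsv(simulate_pics_runs(lib, null_enzyme, noise, seed = seed + 1L),
               "results/runs_null.tsv")
message("wrote runs_positive.tsv / runs_null.tsv (test, inactive, mock, library)")

titrations <- list(
  itc_rvp_uba = list(cell = 64.8, syringe = 796,
                     params = one_site_params(N = 1, Kd = 43, dH = -5)),
  itc_ubl_rvp = list(cell = 133.1, syringe = 2000,
                     params = one_site_params(N = 1, Kd = 310, dH = -5)),
  itc_full_length = list(cell = 97, syringe = 1420,
                         params = two_site_params(175, 575, -5, -5)),
  itc_k48_ub2 = list(cell = 48.5, syringe = 833.5,
                     params = one_site_params(N = 1, Kd = 77, dH = -5)))
for (nm in names(titrations)) {
  cs <- titrations[[nm]]
  protocol <- injection_protocol(1.43, cs$cell, cs$syringe, rep(9, 30))
  ti <- simulate_isotherm(protocol, cs$params, noise_sd = 0, seed = seed)
  write_titration_tsv(ti, file.path("results", paste0(nm, ".tsv")))
}
message("wrote 4 titration TSVs under results/")
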