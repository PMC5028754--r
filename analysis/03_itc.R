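#!/usr/bin/env Rscript
# Stage 3: fit the simulated titrations with the models used for the real
# ones -- single-site fits for the two deletion constructs and the
# diubiquitin titration, a floating-N single-site fit plus a two-site
# (N fixed at 1 per site) fit for full-length protein -- and convert the
# recovered affinities to free energies.

suppressPackageStartupMessages(library(picsitc))

one_site_files <- c(itc_rvp_uba = "results/itc_rvp_uba.tsv",
                    itc_ubl_rvp = "results/itc_ubl_rvp.tsv",
                    itc_k48_ub2 = "results/itc_k48_ub2.tsv")
kds <- numeric()
for (nm in names(one_site_files)) {
  ti <- read_titration_tsv(one_site_files[[nm]])
  fit <- fit_one_site(ti)
  kds[nm] <- fit$params$Kd
  message(sprintf("%s: one-site N = %.3f, Kd = %.1f uM (c = %.2f), dG = %.2f kcal/mol",
                  nm, fit$params$N, fit$params$Kd,
                  wiseman_c(ti$protocol, fit$params), delta_g(fit$params$Kd)))
  write_fit_json(fit, sprintf("results/fit_%s.json", nm))
}

ti_fl <- read_titration_tsv("results/itc_full_length.tsv")
fit1 <- fit_one_site(ti_fl)
message(sprintf("itc_full_length: one-site (floating N) N = %.3f, Kd = %.1f uM",
                fit1$params$N, fit1$params$Kd))
write_fit_json(fit1, "results/fit_itc_full_length_one_site.json")

fit2 <- fit_two_sites(ti_fl)
message(sprintf("itc_full_length: two sites Kd1 = %.1f uM, Kd2 = %.1f uM (chi2 = %.2e)",
                fit2$params$Kd1, fit2$params$Kd2, fit2$chi2))
write_fit_json(fit2, "results/fit_itc_full_length_two_sites.json")

# affinity difference between the two single-domain constructs, as a free
# energy
ratio <- kds[["itc_ubl_rvp"]] / kds[["itc_rvp_uba"]]
message(sprintf("UBL-RVP vs RVP-UBA affinity ratio %.1f-fold -> ddG = %.2f kcal/mol",
                ratio, ddg_ratio(ratio)))
message(sprintf("3-fold Kd ratio at 25 C: ddG = %.2f kcal/mol (%.1f at one decimal)",
                ddg_ratio(3), round(ddg_ratio(3), 1)))
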