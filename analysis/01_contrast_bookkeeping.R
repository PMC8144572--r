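#!/usr/bin/env Rscript
# Contrast bookkeeping for the detergent-solubilized receptor complex:
# solvent electron densities / SLDs across the salt series, DDM belt
# pseudo-atom scattering, and the equivalent CH3 perdeuteration
# parameters. Writes results/contrast_tables.csv and prints a summary.

suppressPackageStartupMessages(library(sasflex))
dir.create("results", showWarnings = FALSE)

salts <- c(0, 0.15, 1.4, 2.8, 4.0)
solv_x <- lapply(salts, solvent_model, d2o_fraction = 0)
solv_n <- lapply(salts, solvent_model, d2o_fraction = 1)

tab_solvent <- data.frame(
  nacl_M = salts,
  rho_e_h2o = sapply(solv_x, `[[`, "rho_e"),
  sld_d2o = sapply(solv_n, `[[`, "sld")
)

tail <- composition_scattering(c(C = 12, H = 25))
head0 <- composition_scattering(c(C = 12, H = 21, O = 11))
head7 <- composition_scattering(c(C = 12, H = 21, O = 11), 1, 7)
tab_belt <- data.frame(
  group = c("tail_CH3", "head_H2O_solvent", "head_D2O_solvent"),
  xray_e = c(9, 10, 10),
  neutron_b_fm = c(9 / 97 * tail$neutron_b, 10 / 181 * head0$neutron_b,
                   10 / 181 * head7$neutron_b),
  equiv_deuteration = c(
    equivalent_deuteration_fraction(9 / 97 * tail$neutron_b),
    NA,
    equivalent_deuteration_fraction(10 / 181 * head7$neutron_b))
)
slds <- belt_slds(d2o_fraction = 1)

write.csv(rbind(
  data.frame(table = "solvent", key = paste0("rho_e@", tab_solvent$nacl_M, "M"),
             value = tab_solvent$rho_e_h2o),
  data.frame(table = "solvent", key = paste0("sld_d2o@", tab_solvent$nacl_M, "M"),
             value = tab_solvent$sld_d2o),
  data.frame(table = "belt", key = paste0("b_", tab_belt$group),
             value = tab_belt$neutron_b_fm),
  data.frame(table = "belt", key = c("f_equiv_tail", "f_equiv_head"),
             value = tab_belt$equiv_deuteration[c(1, 3)]),
  data.frame(table = "belt", key = c("sld_tail", "sld_head"),
             value = unname(slds))),
  "results/contrast_tables.csv", row.names = FALSE)

cat("Solvent scale: water", round(tab_solvent$rho_e_h2o[1], 4),
    "e/A^3 rising ~11% to", round(tab_solvent$rho_e_h2o[5], 4),
    "e/A^3 at 4 M NaCl;\nD2O buffer SLD falls ~3% from",
    signif(tab_solvent$sld_d2o[1], 4), "to",
    signif(tab_solvent$sld_d2o[5], 4), "A^-2 over the same range --\n",
    "the X-ray contrast shifts strongly with salt while the SANS contrast",
    "barely moves, which is why the oligomer series is fitted in SANS.\n")
cat("Belt pseudo-atoms: tail", round(tab_belt$neutron_b_fm[1], 3),
    "fm (f_equiv", round(tab_belt$equiv_deuteration[1], 4), "), head in D2O",
    round(tab_belt$neutron_b_fm[3], 3), "fm (f_equiv",
    round(tab_belt$equiv_deuteration[3], 4), ")\n")
cat("Belt shell SLDs (D2O):", signif(slds[1], 3), "/", signif(slds[2], 3),
    "A^-2 (hydrophobic/hydrophilic)\n")
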