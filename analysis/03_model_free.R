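#!/usr/bin/env Rscript
# Model-free analysis of simulated curves: Guinier fits, regularized
# P(r), peak positions, dimensionless Kratky diagnostics.
# Usage: Rscript analysis/03_model_free.R [--seed <int>]

suppressPackageStartupMessages(library(sasflex))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[which(args == "--seed") + 1] else 1)
dir.create("results", showWarnings = FALSE)

dimer <- make_toy_dimer(toy_model_spec(seed = seed))
dimer_b <- build_belt(dimer, belt_spec())
tripod <- assemble_c3(dimer_b, 90 / sqrt(3), "tripod")
solv_n <- solvent_model(4, 1)
ns <- noise_spec(seed = seed)

report <- list(seed = seed)
for (nm in c("dimer", "tripod")) {
  model <- if (nm == "dimer") dimer_b else tripod
  cv <- simulate_curve(model, solv_n, "neutron", ns, default_q_grid("sans", 121))
  gu <- guinier_fit(cv)
  dmax <- if (nm == "dimer") 260 else 330
  pr <- ift_pr(cv, dmax = dmax)
  mom <- pr_moments(pr)
  peaks <- pr_peaks(pr, 0.05)
  kr <- kratky_dimensionless(cv, gu$rg, gu$i0)
  sel <- kr$qrg <= 12
  write_pr_report(pr, cv, sprintf("results/pr_%s.txt", nm))
  report[[nm]] <- list(rg_guinier = gu$rg, rg_pr = mom$rg, i0 = gu$i0,
                       pr_chi2 = pr$chi2, pr_peaks = peaks,
                       kratky_peak_qrg = kr$qrg[sel][which.max(kr$kratky[sel])])
  cat(sprintf("%s: Rg %.1f A (Guinier) / %.1f A (P(r)); P(r) peaks at %s A; Kratky max at qRg %.1f\n",
              nm, gu$rg, mom$rg, paste(round(peaks), collapse = ", "),
              report[[nm]]$kratky_peak_qrg))
}
cat("The dimer peaks at small r (membrane domain + corona cross-section);\n",
    "the tripod trimer adds the ~90-100 A inter-dimer peak.\n")
jsonlite::write_json(report, "results/model_free.json", auto_unbox = TRUE,
                     digits = NA)
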