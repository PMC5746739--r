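#!/usr/bin/env Rscript
# Canonical core-metabolism network: flux maps deduced from averaged
# labelling data of two cell types, compared with the true weighted fluxes.
#
# Two cell types share the canonical network (glycolysis, oxidative PPP,
# TCA, glyoxylate shunt, PEPCase, biomass outputs) but run different flux
# distributions chosen so their weighted average equals the reference state
# (glucose 100, G6PDH 50, PEPCase 80, ICL 25, biomass 7.56).  Their
# 27-fragment amino-acid MID datasets (80% [1-13C] + 20% [13C6] glucose) are
# averaged 50:50 and a single network is fitted to the average, with
# continuation confidence intervals; the measured glucose uptake (100) pins
# the flux scale.  Scenario A varies internal fluxes only; scenario B also
# varies the biomass output.

library(hetflux)

dir.create("results", showWarnings = FALSE)
net <- build_canonical_network()
param <- free_flux_basis(net)
tracer <- glucose_tracer(frac_1 = 0.8, frac_u = 0.2)
panel <- default_fragment_panel()
ref <- c(upt.net = 100, g6pdh.net = 50, ppc.net = 80, icl.net = 25,
         biomass.net = 7.56)

scenarios <- list(
  `internal fluxes varied` =
    make_balanced_scenario(param, ref,
                           c(100, 30, 60, 10, 7.56),
                           label = "internal fluxes varied"),
  `biomass output varied` =
    make_balanced_scenario(param, ref,
                           c(100, 40, 65, 18, 5.0),
                           label = "biomass output varied"))

all_rows <- list()
for (nm in names(scenarios)) {
  rep_ <- run_mixture_experiment(
    net, scenarios[[nm]], tracer, param, panel = panel,
    settings = fit_settings(multistart = 6, seed = 11),
    extra_measurements = flux_measurements("upt", 100))
  rep_$scenario <- nm
  all_rows[[nm]] <- as.data.frame(rep_)
  cat(sprintf("\n== %s ==\n", nm))
  print(rep_[, c("quantity", "expected", "estimate", "ci_lo", "ci_hi",
                 "percent")], digits = 4)
  fr <- rep_[grepl("\\.net$", rep_$quantity), ]
  out <- with(fr, expected < ci_lo | expected > ci_hi)
  cat(sprintf("fluxes whose 95%% CI excludes the weighted value: %d of %d\n",
              sum(out), nrow(fr)))
}
tab <- do.call(rbind, all_rows)
write.table(tab, "results/03_canonical_mixture.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nAveraged labelling data from heterogeneous populations produce\n",
    "well-defined but wrong flux solutions, with no consistent error\n",
    "direction, and matching errors in gas exchange, respiratory quotient\n",
    "and carbon conversion efficiency.\n", sep = "")
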