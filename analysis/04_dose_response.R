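#!/usr/bin/env Rscript
# Stage 4: single-agent potency.
#
# Converts each agent's viability table to fraction affected against its
# vehicle wells and fits the median-effect model; Dm is reported as the
# IC50.
suppressPackageStartupMessages(library(tnbcsynergy))

files <- c(gemcitabine = "results/data/viability_gemcitabine.csv",
           `UCN-01` = "results/data/viability_ucn01.csv")
rows <- lapply(names(files), function(agent) {
  fit <- fit_median_effect(effect_points(read_viability(files[[agent]])))
  data.frame(agent = agent, m = fit$m, Dm_nM = fit$Dm, r = fit$r,
             n_doses = fit$n)
})
report <- do.call(rbind, rows)
write.table(format(report, digits = 4), "results/potency_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("median-effect fits:\n")
for (i in seq_len(nrow(report))) {
  cat(sprintf("  %-12s m = %.3f, IC50 = %.2f nM, r = %.4f (%d doses)\n",
              report$agent[i], report$m[i], report$Dm_nM[i], report$r[i],
              report$n_doses[i]))
}
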