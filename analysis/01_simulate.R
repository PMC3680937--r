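#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces (under results/data/):
#   - four cross-species expression datasets carrying an 80-gene planted
#     up-regulated signature, with homology map and signature table
#   - two replicate siRNA screens of a 108-gene library with six planted
#     inhibitory genes, for one TNBC line and one control line
#   - single-agent viability curves (gemcitabine-like and UCN-01-like) and
#     a constant-ratio combination simulated at kappa = 0.5
suppressPackageStartupMessages(library(tnbcsynergy))

seed <- 20260925L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, replicates = 2)
coll <- gen_expression_collection(cfg, n_signature = 80, n_background = 120,
                                  effect = 2)
for (i in seq_along(coll$datasets)) {
  write_expression(coll$datasets[[i]], file.path(out, sprintf("expr_ds%d.tsv", i)))
}
write_homology(coll$homology, file.path(out, "homology.tsv"))
write_signature(coll$signature, file.path(out, "signature.tsv"))

planted <- sprintf("SG%03d", c(5, 23, 41, 67, 88, 102))
tumor <- gen_screen(cfg, n_genes = 108, hit_genes = planted,
                    inhibition = 0.5, cell_line = "TNBC1")
ctrl <- gen_screen(sim_config(seed = seed + 1L, replicates = 2),
                   n_genes = 108, hit_genes = planted[4:6],
                   inhibition = 0.5, cell_line = "CTRL")
write_plates(rbind(tumor, ctrl), file.path(out, "screen_plates.csv"))

doses1 <- 10^seq(log10(0.1), 3, length.out = 8)
doses2 <- 10^seq(0, 4, length.out = 8)
write_viability(gen_dose_response(1.3, 20, doses1, reps = 3, noise_sd = 0.03,
                                  seed = seed + 2L, agent = "gemcitabine"),
                file.path(out, "viability_gemcitabine.csv"))
write_viability(gen_dose_response(1.5, 173, doses2, reps = 3, noise_sd = 0.03,
                                  seed = seed + 3L, agent = "UCN-01"),
                file.path(out, "viability_ucn01.csv"))
d1 <- 20 * 2^seq(-3, 2)
write_viability(gen_combination(interaction_spec(1.3, 20, 1.5, 173, kappa = 0.5),
                                cbind(d1, 8.65 * d1), reps = 3,
                                noise_sd = 0.02, seed = seed + 4L,
                                agents = c("gemcitabine", "UCN-01")),
                file.path(out, "viability_combo.csv"))

write_manifest(file.path(out, "manifest.json"), cfg, stage = "simulate",
               planted_hits = planted, combo_kappa = 0.5)
cat("simulated inputs written to", out, "\n")
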