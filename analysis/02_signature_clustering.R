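#!/usr/bin/env Rscript
# Stage 2: cross-species signature projection and clustering.
#
# Collapses probes, maps all datasets onto the signature gene universe
# through the homology table, z-scores per gene within dataset, and
# clusters samples by complete linkage under the uncentered-correlation
# distance. Reports whether the tumor-like samples from all datasets fall
# into one flat cluster at k = 2 (the quantitative version of "tumor-like
# samples cluster together").
suppressPackageStartupMessages(library(tnbcsynergy))

dat <- "results/data"
out <- "results"
datasets <- lapply(list.files(dat, pattern = "^expr_ds\\d+\\.tsv$",
                              full.names = TRUE), read_expression)
homology <- read_homology(file.path(dat, "homology.tsv"))
signature <- read_signature(file.path(dat, "signature.tsv"))

res <- signature_cluster_pipeline(datasets, homology, signature)
write_newick(res$tree, file.path(out, "signature_dendrogram.nwk"))

tum <- colnames(res$matrix$values)[res$matrix$group == "tumor_like"]
cc <- co_cluster(res$tree, k = 2, query = tum)
membership <- data.frame(sample = names(cc$labels),
                         cluster = unname(cc$labels),
                         dataset = res$matrix$dataset,
                         group = res$matrix$group)
write.table(membership, file.path(out, "cluster_membership.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("clustered %d samples on %d signature genes\n",
            ncol(res$matrix$values), length(res$matrix$gene_ids)))
cat(sprintf("tumor-like samples co-cluster at k = 2: %s\n",
            cc$co_clustered))
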