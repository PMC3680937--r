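mk_ds <- function(values, probes, genes,
                  samples = paste0("s", seq_len(ncol(values)))) {
  expression_dataset(probes, genes, values, samples,
                     rep("tumor_like", length(samples)), "human", "test")
}

test_that("probe collapsing keeps the highest-median probe, ties lexicographic", {
  vals <- rbind(c(4, 5, 6), c(6, 7, 8), c(1, 1, 1))
  ds <- mk_ds(vals, c("P1", "P2", "Q1"), c("g1", "g1", "g2"))
  out <- collapse_probes(ds)
  expect_equal(out$probe_ids, c("P2", "Q1"))   # median 7 beats 5; singleton kept
  expect_equal(out$gene_ids, c("g1", "g2"))

  tie <- mk_ds(rbind(c(1, 2, 3), c(3, 2, 1)), c("Pb", "Pa"), c("g", "g"))
  expect_equal(collapse_probes(tie)$probe_ids, "Pa")
})

test_that("homology mapping keeps strict 1:1 pairs and the common universe", {
  d_h <- mk_ds(rbind(c(1, 2), c(3, 4), c(5, 6)), paste0("hp", 1:3),
               c("HA", "HB", "HC"))
  d_m <- expression_dataset(paste0("mp", 1:2), c("MA", "MB"),
                            rbind(c(1, 2), c(3, 4)), c("t1", "t2"),
                            rep("tumor_like", 2), "mouse", "marray")
  hom <- data.frame(gene_a = c("HA", "HB", "HB", "HC"),
                    gene_b = c("MA", "MB", "MBx", "MC"))
  sig <- data.frame(gene_id = c("HA", "HB", "HC"), direction = "up")
  # HB maps one-to-many -> dropped; HC's homolog MC absent from mouse data
  expect_message(res <- map_to_common_universe(list(d_h, d_m), hom, sig),
                 "not one-to-one")
  expect_equal(res$universe, "HA")
  for (ds in res$datasets) expect_equal(ds$gene_ids, "HA")
  # gene absent from one dataset is dropped even with a clean map
  hom2 <- data.frame(gene_a = c("HA", "HC"), gene_b = c("MA", "MC"))
  res2 <- suppressMessages(map_to_common_universe(list(d_h, d_m), hom2, sig))
  expect_equal(res2$universe, "HA")
  expect_error(suppressMessages(map_to_common_universe(
    list(d_h, d_m), data.frame(gene_a = "HX", gene_b = "MX"), sig)),
    "no signature genes")
})

test_that("z-scoring standardizes per gene with sample sd and drops constants", {
  ds <- mk_ds(rbind(c(1, 2, 3), c(5, 5, 5)), c("p1", "p2"), c("g1", "g2"))
  expect_warning(out <- zscore_genes(ds), "zero-variance")
  expect_equal(out$gene_ids, "g1")
  expect_equal(as.numeric(out$values), c(-1, 0, 1))

  big <- mk_ds(matrix(rnorm(50), 10, 5), paste0("p", 1:10),
               paste0("g", 1:10))
  z <- zscore_genes(big)
  expect_equal(unname(rowMeans(z$values)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z$values, 1, sd)), rep(1, 10),
               tolerance = 1e-9)
  one <- mk_ds(matrix(1, 2, 1), c("a", "b"), c("g1", "g2"))
  expect_error(zscore_genes(one), ">= 2 samples")
})

test_that("the clustering pipeline is invariant to sample column order", {
  coll <- gen_expression_collection(sim_config(seed = 3, samples = 3),
                                    40, 40, effect = 2)
  shuffled <- lapply(coll$datasets, function(ds) {
    set.seed(99)
    perm <- sample(ncol(ds$values))
    expression_dataset(ds$probe_ids, ds$gene_ids,
                       ds$values[, perm, drop = FALSE],
                       ds$sample_ids[perm], ds$groups[perm],
                       ds$species, ds$platform)
  })
  r1 <- suppressMessages(signature_cluster_pipeline(
    coll$datasets, coll$homology, coll$signature))
  r2 <- suppressMessages(signature_cluster_pipeline(
    shuffled, coll$homology, coll$signature))
  for (k in c(2, 4, 8)) {
    c1 <- co_cluster(r1$tree, k)$labels
    c2 <- co_cluster(r2$tree, k)$labels
    expect_true(same_partition(c1[sort(names(c1))], c2[sort(names(c1))]))
  }
  expect_equal(sort(r1$tree$height), sort(r2$tree$height),
               tolerance = 1e-12)
})
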