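#' Collapse multiple probes per gene to the brightest probe
#'
#' When several array probes map to the same gene, only the probe with the
#' highest median signal across all samples is retained. Ties are broken by
#' keeping the lexicographically smallest probe id, so collapsing is
#' deterministic.
#'
#' @param dataset An [expression_dataset()].
#' @return The dataset with one probe per gene.
#' @export
collapse_probes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  med <- apply(dataset$values, 1L, stats::median)
  ord <- order(dataset$gene_ids, -med, dataset$probe_ids)
  keep <- ord[!duplicated(dataset$gene_ids[ord])]
  keep <- sort(keep)   # preserve original probe order
  expression_dataset(dataset$probe_ids[keep], dataset$gene_ids[keep],
                     dataset$values[keep, , drop = FALSE],
                     dataset$sample_ids, dataset$groups,
                     dataset$species, dataset$platform)
}

#' Restrict datasets to a common signature gene universe
#'
#' Translates gene identifiers across species through a homology table,
#' keeps only strictly one-to-one homology pairs (one-to-many and
#' many-to-many pairs are dropped, with a message reporting the count), and
#' restricts every dataset to the signature genes present in all datasets
#' after translation. Rows are reordered identically, so the datasets can
#' be column-bound after standardization.
#'
#' @param datasets List of probe-collapsed [expression_dataset()]s.
#' @param homology data.frame with columns `gene_a`, `gene_b` (e.g. human
#'   and mouse Entrez-style ids). Dataset gene ids matching `gene_a` are
#'   kept as-is; others are translated `gene_b -> gene_a`.
#' @param signature data.frame with columns `gene_id` (in the `gene_a`
#'   namespace) and `direction`.
#' @return List with `universe` (character vector of retained gene ids) and
#'   `datasets` (relabeled, restricted, identically row-ordered).
#' @export
map_to_common_universe <- function(datasets, homology, signature) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  if (anyDuplicated(signature$gene_id)) {
    stop("signature gene ids must be unique", call. = FALSE)
  }
  # strict 1:1 filter on the homology map
  bad <- homology$gene_a %in% homology$gene_a[duplicated(homology$gene_a)] |
         homology$gene_b %in% homology$gene_b[duplicated(homology$gene_b)]
  if (any(bad)) {
    message(sum(bad), " homology pairs dropped (not one-to-one)")
    homology <- homology[!bad, , drop = FALSE]
  }
  b_to_a <- stats::setNames(homology$gene_a, homology$gene_b)

  relabeled <- lapply(datasets, function(ds) {
    ids <- ds$gene_ids
    translated <- ifelse(ids %in% homology$gene_a, ids,
                         unname(b_to_a[ids]))
    keep <- !is.na(translated)
    if (!any(keep)) {
      stop("no signature genes shared by all datasets", call. = FALSE)
    }
    expression_dataset(ds$probe_ids[keep], translated[keep],
                       ds$values[keep, , drop = FALSE],
                       ds$sample_ids, ds$groups, ds$species, ds$platform)
  })

  universe <- signature$gene_id
  for (ds in relabeled) universe <- intersect(universe, ds$gene_ids)
  dropped <- setdiff(signature$gene_id, universe)
  if (length(dropped)) {
    message(length(dropped),
            " signature genes absent from at least one dataset, dropped")
  }
  if (length(universe) == 0L) {
    stop("no signature genes shared by all datasets", call. = FALSE)
  }
  restricted <- lapply(relabeled, function(ds) {
    idx <- match(universe, ds$gene_ids)
    expression_dataset(ds$probe_ids[idx], ds$gene_ids[idx],
                       ds$values[idx, , drop = FALSE],
                       ds$sample_ids, ds$groups, ds$species, ds$platform)
  })
  list(universe = universe, datasets = restricted)
}

#' Standardize each gene within a dataset (z-score transformation)
#'
#' Per gene and per dataset, expression is centered and scaled to mean 0
#' and unit sample (n-1) standard deviation. Genes with zero variance carry
#' no clustering information and corrupt correlation norms; they are
#' dropped with a warning.
#'
#' @param dataset An [expression_dataset()] with >= 2 samples.
#' @return The standardized dataset (possibly with fewer genes).
#' @export
zscore_genes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (ncol(dataset$values) < 2L) {
    stop("z-scoring needs >= 2 samples", call. = FALSE)
  }
  mu <- rowMeans(dataset$values)
  sdev <- apply(dataset$values, 1L, stats::sd)
  zero <- sdev == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance genes dropped from ",
            dataset$platform, call. = FALSE)
  }
  keep <- !zero
  z <- (dataset$values[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  expression_dataset(dataset$probe_ids[keep], dataset$gene_ids[keep], z,
                     dataset$sample_ids, dataset$groups,
                     dataset$species, dataset$platform)
}

#' Integrate standardized datasets into one gene-by-sample matrix
#'
#' Column-binds identically row-ordered standardized datasets and records
#' each sample's dataset of origin and group annotation. Genes dropped from
#' any dataset during standardization are removed everywhere so the row
#' sets agree.
#'
#' @param datasets List of z-scored, identically gene-ordered datasets.
#' @return Object of class `integrated_matrix`: list with `values`
#'   (genes x samples), `dataset` and `group` (per-sample), `gene_ids`.
#' @export
integrate_datasets <- function(datasets) {
  common <- Reduce(intersect, lapply(datasets, function(d) d$gene_ids))
  if (length(common) == 0L) stop("no genes shared after standardization",
                                 call. = FALSE)
  mats <- lapply(datasets, function(d) {
    d$values[match(common, d$gene_ids), , drop = FALSE]
  })
  values <- do.call(cbind, mats)
  rownames(values) <- common
  structure(list(values = values,
                 gene_ids = common,
                 dataset = unlist(lapply(datasets, function(d)
                   rep(d$platform, length(d$sample_ids)))),
                 group = unlist(lapply(datasets, function(d) d$groups))),
            class = "integrated_matrix")
}

#' Full cross-species signature clustering pipeline
#'
#' Chains the integration steps: probe collapsing, homology mapping onto
#' the signature universe, per-dataset per-gene z-scoring, column binding,
#' and complete-linkage clustering of samples under the
#' uncentered-correlation distance.
#'
#' @param datasets List of [expression_dataset()]s.
#' @param homology,signature See [map_to_common_universe()].
#' @return List with `matrix` (the `integrated_matrix`) and `tree` (an
#'   `hclust` object from [cluster_complete()]).
#' @export
#' @examples
#' coll <- gen_expression_collection(sim_config(seed = 1), 80, 120, effect = 2)
#' res <- signature_cluster_pipeline(coll$datasets, coll$homology,
#'                                   coll$signature)
#' res$tree
signature_cluster_pipeline <- function(datasets, homology, signature) {
  collapsed <- lapply(datasets, collapse_probes)
  mapped <- map_to_common_universe(collapsed, homology, signature)
  standardized <- lapply(mapped$datasets, zscore_genes)
  integrated <- integrate_datasets(standardized)
  list(matrix = integrated, tree = cluster_complete(integrated))
}
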