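#' Simulate a cross-species expression collection with a planted signature
#'
#' Generates `config$n_datasets` expression datasets spanning two species
#' with distinct probe namespaces, a one-to-one homology map linking the
#' species' gene identifiers, and an up-regulated signature gene set. Each
#' dataset contains a tumor-like and a normal-like sample group; signature
#' genes are shifted upward by `effect` log2 units in tumor-like samples
#' only. Datasets differ in overall scale and baseline offset, so downstream
#' per-dataset standardization is required before integration — mirroring
#' the situation when mouse tumor arrays, mouse and human cell-line arrays
#' and a public cell-line panel must be co-clustered on one signature.
#'
#' Every fourth gene carries two sibling probes whose medians differ by a
#' fixed offset, so probe collapsing has a decidable answer.
#'
#' @param config A [sim_config()]; `samples` is the per-group sample count
#'   and `expr_noise_sd` the within-group noise sd (log2 units).
#' @param n_signature Number of signature (up-regulated) genes.
#' @param n_background Number of non-signature genes.
#' @param effect Log2-unit shift of signature genes in tumor-like samples;
#'   must be >= 0 (the signature is defined as up-regulated).
#'
#' @return A list with components `datasets` (list of
#'   [expression_dataset()]), `homology` (data.frame `gene_a`, `gene_b`:
#'   human and mouse gene ids, strictly 1:1), and `signature` (data.frame
#'   `gene_id`, `direction`, in the human namespace).
#' @export
#' @examples
#' coll <- gen_expression_collection(sim_config(seed = 1),
#'                                   n_signature = 80, n_background = 120,
#'                                   effect = 2)
#' length(coll$datasets)
#' nrow(coll$signature)
gen_expression_collection <- function(config, n_signature, n_background,
                                      effect = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (n_signature < 1 || n_background < 1) {
    stop("n_signature and n_background must be >= 1", call. = FALSE)
  }
  if (!is.finite(effect) || effect < 0) {
    stop("effect must be >= 0: the signature is up-regulated", call. = FALSE)
  }
  set.seed(config$seed)

  n_genes <- n_signature + n_background
  human_ids <- sprintf("GH%04d", seq_len(n_genes))
  mouse_ids <- sprintf("GM%04d", seq_len(n_genes))
  sig_idx <- seq_len(n_signature)

  # gene-level baseline, shared across datasets so the signature is the
  # same biological axis everywhere
  mu <- stats::rnorm(n_genes, mean = 8, sd = 1.5)
  dup <- which(seq_len(n_genes) %% 4L == 0L)   # genes with a sibling probe

  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    species <- if (d %% 2L == 1L) "human" else "mouse"
    gene_ids <- if (species == "human") human_ids else mouse_ids
    platform <- sprintf("%s_array_sim%d", substr(species, 1, 2), d)
    scale_d <- stats::runif(1, 0.8, 1.3)
    offset_d <- stats::rnorm(1, 0, 0.5)

    n_s <- config$samples
    groups <- rep(c("tumor_like", "normal_like"), each = n_s)
    sample_ids <- sprintf("ds%d_%s_%d", d,
                          rep(c("tumor", "normal"), each = n_s),
                          rep(seq_len(n_s), 2L))

    shift <- matrix(0, n_genes, 2L * n_s)
    shift[sig_idx, groups == "tumor_like"] <- effect
    base <- matrix(mu, n_genes, 2L * n_s) + shift +
      matrix(stats::rnorm(n_genes * 2L * n_s, 0, config$expr_noise_sd),
             n_genes, 2L * n_s)
    vals <- scale_d * base + offset_d

    # primary probes, then dimmer sibling probes for every fourth gene
    probe_ids <- sprintf("%s_p%04d_a", substr(platform, 1, 2), seq_len(n_genes))
    sib_vals <- vals[dup, , drop = FALSE] - 1.5 +
      matrix(stats::rnorm(length(dup) * 2L * n_s, 0, config$expr_noise_sd / 2),
             length(dup), 2L * n_s)
    probe_ids <- c(probe_ids, sprintf("%s_p%04d_b", substr(platform, 1, 2), dup))
    datasets[[d]] <- expression_dataset(
      probe_ids = probe_ids,
      gene_ids = c(gene_ids, gene_ids[dup]),
      values = rbind(vals, sib_vals),
      sample_ids = sample_ids,
      groups = groups,
      species = species,
      platform = platform)
  }

  list(datasets = datasets,
       homology = data.frame(gene_a = human_ids, gene_b = mouse_ids,
                             stringsAsFactors = FALSE),
       signature = data.frame(gene_id = human_ids[sig_idx],
                              direction = "up",
                              stringsAsFactors = FALSE))
}
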