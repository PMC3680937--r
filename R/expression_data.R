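#' Construct an expression dataset
#'
#' A probe-by-sample matrix of log-scale normalized intensities with probe,
#' gene, species and platform annotation, as produced by one microarray
#' experiment after preprocessing. Validates that dimensions agree, probe ids
#' are unique and no values are missing.
#'
#' @param probe_ids Character vector of probe identifiers, unique.
#' @param gene_ids Character vector of gene identifiers, one per probe
#'   (Entrez-style; several probes may share a gene).
#' @param values Numeric matrix, probes x samples, log2 scale, no `NA`.
#' @param sample_ids Character vector of sample labels.
#' @param groups Character vector of per-sample group annotations (for the
#'   synthetic collections: `"tumor_like"` or `"normal_like"`).
#' @param species,platform Single-string tags.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(probe_ids, gene_ids, values, sample_ids,
                               groups, species, platform) {
  values <- as.matrix(values)
  if (length(probe_ids) == 0L || ncol(values) == 0L) {
    stop("empty dataset", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    stop("probe_ids must be unique within a dataset", call. = FALSE)
  }
  if (nrow(values) != length(probe_ids) || length(gene_ids) != length(probe_ids)) {
    stop("probe annotation length does not match matrix rows", call. = FALSE)
  }
  if (ncol(values) != length(sample_ids) || length(groups) != length(sample_ids)) {
    stop("sample annotation length does not match matrix columns", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite with no missing entries",
         call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(probe_ids = as.character(probe_ids),
                 gene_ids = as.character(gene_ids),
                 values = values,
                 sample_ids = as.character(sample_ids),
                 groups = as.character(groups),
                 species = species,
                 platform = platform),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probes x %d samples [%s / %s]\n",
              nrow(x$values), ncol(x$values), x$species, x$platform))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)
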