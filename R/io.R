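#' @keywords internal
check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' @keywords internal
check_numeric <- function(v, name, what, nonneg = FALSE) {
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric or missing %s at row %d",
                 what, name, bad[1]), call. = FALSE)
  }
  if (nonneg) {
    neg <- which(v < 0)
    if (length(neg)) {
      stop(sprintf("%s: negative %s at row %d", what, name, neg[1]),
           call. = FALSE)
    }
  }
  invisible(v)
}

#' Write / read an expression dataset (TSV plus JSON sidecar)
#'
#' The TSV holds `probe_id`, `gene_id` and one column per sample; the
#' sidecar `<path>.json` records species, platform and per-sample group
#' annotations. Reading validates all dataset invariants (unique probes,
#' no missing values, matching dimensions).
#'
#' @param dataset An [expression_dataset()].
#' @param path TSV file path; the sidecar is written next to it.
#' @return `write_expression` the path invisibly; `read_expression` an
#'   [expression_dataset()].
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- data.frame(probe_id = dataset$probe_ids,
                    gene_id = dataset$gene_ids,
                    dataset$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(species = dataset$species,
                            platform = dataset$platform,
                            sample_ids = dataset$sample_ids,
                            groups = dataset$groups),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  check_columns(tab, c("probe_id", "gene_id"), "expression file")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sample_cols <- setdiff(names(tab), c("probe_id", "gene_id"))
  vals <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  for (j in seq_len(ncol(vals))) {
    check_numeric(vals[, j], sample_cols[j], "expression file")
  }
  if (anyDuplicated(tab$probe_id)) {
    stop("expression file: duplicate probe_id at row ",
         which(duplicated(tab$probe_id))[1], call. = FALSE)
  }
  expression_dataset(tab$probe_id, tab$gene_id, vals,
                     meta$sample_ids, meta$groups,
                     meta$species, meta$platform)
}

#' Write / read a homology table (two-column TSV)
#'
#' @param homology data.frame with columns `gene_a`, `gene_b`.
#' @param path TSV path.
#' @export
write_homology <- function(homology, path) {
  check_columns(homology, c("gene_a", "gene_b"), "homology table")
  utils::write.table(homology, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_homology
#' @export
read_homology <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(tab, c("gene_a", "gene_b"), "homology file")
  tab
}

#' Write / read a signature gene set (TSV: gene_id, direction)
#'
#' @param signature data.frame with `gene_id`, `direction` (up/down).
#' @param path TSV path.
#' @export
write_signature <- function(signature, path) {
  check_columns(signature, c("gene_id", "direction"), "signature table")
  utils::write.table(signature, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(tab, c("gene_id", "direction"), "signature file")
  if (anyDuplicated(tab$gene_id)) {
    stop("signature file: duplicate gene_id at row ",
         which(duplicated(tab$gene_id))[1], call. = FALSE)
  }
  bad <- which(!tab$direction %in% c("up", "down"))
  if (length(bad)) {
    stop("signature file: direction must be 'up' or 'down' at row ",
         bad[1], call. = FALSE)
  }
  tab
}

#' Write / read screen plate data (CSV)
#'
#' Columns: `plate_id, screen_id, cell_line, well, content_type, gene_id,
#' absorbance`. Reading rejects missing columns, non-numeric or negative
#' absorbance (with the offending row number), unknown content types and
#' duplicate plate/well keys.
#'
#' @param plates Long-format plate data.frame.
#' @param path CSV path.
#' @export
write_plates <- function(plates, path) {
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plates
#' @export
read_plates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, c("plate_id", "screen_id", "cell_line", "well",
                       "content_type", "gene_id", "absorbance"),
                "plate file")
  check_numeric(tab$absorbance, "absorbance", "plate file", nonneg = TRUE)
  ok_types <- c("library", "NTS", "cyclophilin_B", "PLK1", "cell_death")
  bad <- which(!tab$content_type %in% ok_types)
  if (length(bad)) {
    stop("plate file: unknown content_type at row ", bad[1], call. = FALSE)
  }
  key <- paste(tab$screen_id, tab$plate_id, tab$well)
  if (anyDuplicated(key)) {
    stop("plate file: duplicate well key at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  tab$gene_id[tab$gene_id == ""] <- NA_character_
  tab
}

#' Write / read viability tables (CSV)
#'
#' Columns: `experiment_id, agent1, dose1_nM, agent2, dose2_nM, replicate,
#' signal, is_vehicle`. Doses are stored in nM; `read_viability` can
#' convert from other units on load.
#'
#' @param viability Viability data.frame.
#' @param path CSV path.
#' @param dose_unit Unit of the dose columns in the file: `"nM"`
#'   (default), `"pM"` or `"uM"`; converted to nM on load.
#' @export
write_viability <- function(viability, path) {
  utils::write.csv(viability, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_viability
#' @export
read_viability <- function(path, dose_unit = "nM") {
  fac <- unname(c(pM = 1e-3, nM = 1, uM = 1e3)[dose_unit])
  if (is.na(fac)) stop("dose_unit must be pM, nM or uM", call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, c("experiment_id", "agent1", "dose1_nM", "replicate",
                       "signal", "is_vehicle"), "viability file")
  check_numeric(tab$signal, "signal", "viability file")
  tab$is_vehicle <- as.logical(tab$is_vehicle)
  nz <- which(!tab$is_vehicle & (!is.finite(tab$dose1_nM) | tab$dose1_nM <= 0))
  if (length(nz)) {
    stop("viability file: non-positive dose at row ", nz[1], call. = FALSE)
  }
  tab$dose1_nM <- tab$dose1_nM * fac
  if (!is.null(tab$dose2_nM)) tab$dose2_nM <- tab$dose2_nM * fac
  tab
}

#' Export a dendrogram as newick
#'
#' Converts the `hclust` tree to a phylogeny (branch lengths derived from
#' the merge heights) and writes newick text.
#'
#' @param tree An `hclust` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed and package version of a run as JSON,
#' sufficient to re-run the stage bit-identically.
#'
#' @param path Output JSON path.
#' @param config A [sim_config()] or any named list of parameters.
#' @param ... Further named fields to record.
#' @export
write_manifest <- function(path, config, ...) {
  jsonlite::write_json(
    list(package = "tnbcsynergy",
         version = as.character(utils::packageVersion("tnbcsynergy")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(config), ...),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
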