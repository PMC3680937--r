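#' Normalize screen plates to the non-targeting control
#'
#' For every plate of every screen, divides the mean absorbance of each
#' library gene's wells by the mean absorbance of that plate's non-targeting
#' siRNA (NTS) wells, yielding per-gene viability as a fraction of the
#' negative control. Positive and transfection controls are excluded from
#' the output.
#'
#' @param plates Long-format plate data as produced by [gen_screen()] or
#'   [read_plates()].
#' @return data.frame with columns `screen_id`, `cell_line`, `plate_id`,
#'   `gene_id`, `viability`.
#' @export
normalize_to_nts <- function(plates) {
  req <- c("plate_id", "screen_id", "cell_line", "well", "content_type",
           "gene_id", "absorbance")
  if (!all(req %in% names(plates))) {
    stop("plate data missing columns: ",
         paste(setdiff(req, names(plates)), collapse = ", "), call. = FALSE)
  }
  key <- interaction(plates$screen_id, plates$plate_id, drop = TRUE)
  out <- lapply(split(plates, key), function(pl) {
    nts <- pl$absorbance[pl$content_type == "NTS"]
    if (length(nts) == 0L) {
      stop(sprintf("plate %s / screen %s has no NTS wells",
                   pl$plate_id[1], pl$screen_id[1]), call. = FALSE)
    }
    nts_mean <- mean(nts)
    if (!is.finite(nts_mean) || nts_mean <= 0) {
      stop(sprintf("plate %s / screen %s has non-positive NTS mean",
                   pl$plate_id[1], pl$screen_id[1]), call. = FALSE)
    }
    lib <- pl[pl$content_type == "library", , drop = FALSE]
    via <- tapply(lib$absorbance, lib$gene_id, mean) / nts_mean
    data.frame(screen_id = pl$screen_id[1], cell_line = pl$cell_line[1],
               plate_id = pl$plate_id[1], gene_id = names(via),
               viability = as.numeric(via), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-plate z-scores of normalized viability
#'
#' Standardizes each gene's NTS-normalized viability against the mean and
#' sample standard deviation of the library genes on its own plate. Control
#' wells never enter the plate statistics (they are removed during
#' normalization); genes split across plates are scored on their own plate.
#'
#' @param normalized Output of [normalize_to_nts()].
#' @return The input with an added `z` column.
#' @export
plate_zscores <- function(normalized) {
  key <- interaction(normalized$screen_id, normalized$plate_id, drop = TRUE)
  out <- lapply(split(normalized, key), function(pl) {
    if (nrow(pl) < 3L) {
      stop(sprintf("plate %s / screen %s has fewer than 3 library genes",
                   pl$plate_id[1], pl$screen_id[1]), call. = FALSE)
    }
    s <- stats::sd(pl$viability)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("plate %s / screen %s has zero spread",
                   pl$plate_id[1], pl$screen_id[1]), call. = FALSE)
    }
    pl$z <- (pl$viability - mean(pl$viability)) / s
    pl
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble a gene-by-screen z-score matrix
#'
#' @param zscores Output of [plate_zscores()].
#' @return List with `z` (genes x screens numeric matrix) and `screens`
#'   (data.frame `screen_id`, `cell_line`).
#' @export
hit_table <- function(zscores) {
  screens <- unique(zscores[, c("screen_id", "cell_line")])
  genes <- sort(unique(zscores$gene_id))
  z <- matrix(NA_real_, length(genes), nrow(screens),
              dimnames = list(genes, screens$screen_id))
  for (i in seq_len(nrow(zscores))) {
    z[zscores$gene_id[i], zscores$screen_id[i]] <- zscores$z[i]
  }
  if (anyNA(z)) stop("incomplete z table: some gene/screen pairs missing",
                     call. = FALSE)
  list(z = z, screens = screens)
}

#' Call hits per cell line from a z-score matrix
#'
#' A gene is a hit for a cell line when its z-score is at or below `tau` in
#' every replicate screen of that line (growth inhibition pushes z
#' negative).
#'
#' @param z Genes x screens numeric matrix.
#' @param screen_lines Character vector, the cell line of each screen
#'   column.
#' @param tau Negative z threshold; default -1.4.
#' @return Named list of hit gene character vectors, one per cell line.
#' @export
#' @examples
#' z <- tnbc_screen_zscores()
#' call_hits(z$z, z$screens$cell_line, tau = -1.4)
call_hits <- function(z, screen_lines, tau = -1.4) {
  if (!is.matrix(z) || nrow(z) == 0L) stop("empty z table", call. = FALSE)
  if (anyNA(z) || any(!is.finite(z))) stop("z table must be finite",
                                           call. = FALSE)
  if (!is.finite(tau) || tau >= 0) stop("tau must be negative", call. = FALSE)
  if (length(screen_lines) != ncol(z)) {
    stop("screen_lines must match z columns", call. = FALSE)
  }
  lines <- unique(screen_lines)
  hits <- lapply(lines, function(ln) {
    cols <- which(screen_lines == ln)
    rownames(z)[apply(z[, cols, drop = FALSE] <= tau, 1L, all)]
  })
  names(hits) <- lines
  hits
}

#' Classify tumor-selective genes
#'
#' Compares per-line hit sets against the tumor and control lines:
#' `selective` genes are hits in every tumor line but not the control line
#' (candidate tumor-specific dependencies), `nonselective` genes are hits in
#' every line including the control (generic proliferation genes), all
#' others are `non_hit`.
#'
#' @param hits Named list from [call_hits()].
#' @param tumor_lines Character vector of tumor cell-line names (>= 1).
#' @param control_line Single non-tumorigenic control line name.
#' @return data.frame with columns `gene_id` and `call`.
#' @export
classify_selectivity <- function(hits, tumor_lines, control_line) {
  if (length(control_line) != 1L || !control_line %in% names(hits)) {
    stop("exactly one control line present in the hit list is required",
         call. = FALSE)
  }
  if (length(tumor_lines) < 1L || !all(tumor_lines %in% names(hits))) {
    stop("tumor lines missing from the hit list", call. = FALSE)
  }
  genes <- sort(unique(unlist(hits)))
  in_all_tumor <- vapply(genes, function(g)
    all(vapply(tumor_lines, function(ln) g %in% hits[[ln]], logical(1))),
    logical(1))
  in_control <- genes %in% hits[[control_line]]
  call <- ifelse(in_all_tumor & !in_control, "selective",
                 ifelse(in_all_tumor & in_control, "nonselective", "non_hit"))
  data.frame(gene_id = genes, call = call, stringsAsFactors = FALSE)
}

#' Summarize siRNA pool deconvolution
#'
#' When a pooled siRNA hit is deconvoluted, its four individual oligos are
#' transfected separately and growth is expressed as a percentage of the
#' non-targeting reference. The pool is considered on-target confirmed when
#' at least three of the four oligos suppress growth to at or below the
#' activity threshold.
#'
#' @param oligo_signals Numeric vector of 4 per-oligo absorbances.
#' @param reference Absorbance of the non-targeting control (> 0).
#' @param activity_threshold Percent-growth cutoff for an active oligo
#'   (default 70).
#' @return List with `percent_growth` (length 4), `n_active`, `confirmed`.
#' @export
deconvolution_summary <- function(oligo_signals, reference,
                                  activity_threshold = 70) {
  if (length(oligo_signals) != 4L) {
    stop("deconvolution requires exactly 4 oligo measurements", call. = FALSE)
  }
  if (!is.finite(reference) || reference <= 0) {
    stop("reference signal must be > 0", call. = FALSE)
  }
  pct <- 100 * oligo_signals / reference
  n_active <- sum(pct <= activity_threshold)
  list(percent_growth = pct, n_active = n_active,
       confirmed = n_active >= 3L)
}

#' Published-style z-scores for the six top screen hits
#'
#' The z-score matrix of the six strongest hits from a TNBC siRNA
#' proliferation screen — two replicate screens in MDA-MB-231 cells plus
#' confirmation screens in Hs578T (TNBC) and the non-tumorigenic MCF10A
#' line — bundled as a worked example for hit calling and selectivity
#' classification.
#'
#' @return List with `z` (6 x 4 matrix) and `screens` (data.frame
#'   `screen_id`, `cell_line`, `role`).
#' @export
tnbc_screen_zscores <- function() {
  path <- system.file("extdata", "tnbc_screen_zscores.tsv",
                      package = "tnbcsynergy", mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE)
  z <- as.matrix(tab[, -1, drop = FALSE])
  rownames(z) <- tab[[1]]
  screens <- data.frame(
    screen_id = colnames(z),
    cell_line = c("MB231", "MB231", "Hs578T", "MCF10A"),
    role = c("tumor", "tumor", "tumor", "control"),
    stringsAsFactors = FALSE)
  list(z = z, screens = screens)
}
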