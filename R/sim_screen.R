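#' Well labels of a 96-well plate
#'
#' @param interior If `TRUE`, only the interior 60 wells (rows B-G, columns
#'   2-11), the region used for library siRNAs to avoid edge effects.
#' @return Character vector of well labels ("A01" ... "H12").
#' @export
plate_wells <- function(interior = FALSE) {
  rows <- if (interior) LETTERS[2:7] else LETTERS[1:8]
  cols <- if (interior) 2:11 else 1:12
  as.vector(t(outer(rows, cols, function(r, c) sprintf("%s%02d", r, c))))
}

#' Simulate replicate siRNA screen plate sets
#'
#' Lays out `n_genes` library siRNA pools over the interior 60 wells of as
#' many 96-well plates as needed (`ceiling(n_genes / 60)` per replicate
#' screen) and simulates MTS absorbance. Each plate carries three
#' non-targeting siRNA (NTS) wells, a cyclophilin-B transfection control, a
#' PLK1 positive control and a cell-death control on edge wells of row A.
#' Genes in `hit_genes` reduce expected absorbance to
#' `(1 - inhibition)` times the NTS level; all other library genes sit at
#' the NTS level. Wells receive multiplicative log-normal noise with
#' coefficient of variation `config$well_cv`. One full plate set is
#' generated per replicate screen (`config$replicates` screens).
#'
#' The PLK1 and cell-death controls use inhibitions of at least 0.8 and
#' 0.95 (raised to `inhibition` if that is larger), so positive-control
#' wells never read above planted hit wells in expectation.
#'
#' @param config A [sim_config()]; uses `well_cv` and `replicates`.
#' @param n_genes Library size; gene ids are `SG001`, `SG002`, ...
#' @param hit_genes Character vector of planted inhibitory genes (subset of
#'   the library).
#' @param inhibition Planted fractional growth inhibition, in `[0, 1)`.
#' @param cell_line Label recorded in the `cell_line` column.
#' @param baseline Expected NTS-well absorbance (OD units).
#'
#' @return Long-format data.frame with columns `plate_id`, `screen_id`,
#'   `cell_line`, `well`, `content_type`
#'   (`library`/`NTS`/`cyclophilin_B`/`PLK1`/`cell_death`), `gene_id`
#'   (`NA` for controls) and `absorbance`.
#' @export
#' @examples
#' plates <- gen_screen(sim_config(seed = 1, replicates = 2), n_genes = 108,
#'                      hit_genes = c("SG001", "SG002"), inhibition = 0.5)
#' table(plates$screen_id, plates$plate_id)
gen_screen <- function(config, n_genes, hit_genes = character(),
                       inhibition = 0.5, cell_line = "SIMLINE",
                       baseline = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (!is.finite(inhibition) || inhibition < 0 || inhibition >= 1) {
    stop("inhibition must lie in [0, 1)", call. = FALSE)
  }
  genes <- sprintf("SG%03d", seq_len(n_genes))
  missing <- setdiff(hit_genes, genes)
  if (length(missing)) {
    stop("hit genes not in the library: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(config$seed)

  interior <- plate_wells(interior = TRUE)
  n_plates <- ceiling(n_genes / 60)
  control_wells <- c("A02", "A03", "A04", "A05", "A06", "A07")
  control_types <- c("NTS", "NTS", "NTS", "cyclophilin_B", "PLK1", "cell_death")
  plk1_inh <- max(0.8, inhibition)
  death_inh <- max(0.95, inhibition)
  control_expect <- baseline * c(1, 1, 1, 1, 1 - plk1_inh, 1 - death_inh)

  cv <- config$well_cv
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) {
    if (cv == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  out <- vector("list", config$replicates * n_plates)
  k <- 0L
  for (r in seq_len(config$replicates)) {
    screen_id <- sprintf("%s_s%d", cell_line, r)
    for (p in seq_len(n_plates)) {
      idx <- ((p - 1L) * 60L + 1L):min(p * 60L, n_genes)
      plate_genes <- genes[idx]
      expect <- baseline * ifelse(plate_genes %in% hit_genes,
                                  1 - inhibition, 1)
      k <- k + 1L
      out[[k]] <- data.frame(
        plate_id = sprintf("P%02d", p),
        screen_id = screen_id,
        cell_line = cell_line,
        well = c(control_wells, interior[seq_along(plate_genes)]),
        content_type = c(control_types, rep("library", length(plate_genes))),
        gene_id = c(rep(NA_character_, length(control_wells)), plate_genes),
        absorbance = c(control_expect, expect) *
          noise(length(control_wells) + length(plate_genes)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
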