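#' Simulation configuration
#'
#' Bundles the random seed, noise levels and problem sizes shared by the
#' synthetic-data generators. Identical configurations produce bit-identical
#' output from every generator.
#'
#' @param seed Integer random seed.
#' @param well_cv Multiplicative well-to-well coefficient of variation for
#'   plate absorbance (fraction, e.g. 0.05 for 5%).
#' @param viability_noise_sd Additive Gaussian noise on the viability scale
#'   (fraction of vehicle signal).
#' @param expr_noise_sd Within-group expression noise, sd in log2 units.
#' @param n_datasets Number of expression datasets in a collection.
#' @param genes Number of genes per simulated universe.
#' @param samples Samples per group (tumor-like and normal-like) per dataset.
#' @param doses Number of dose levels in a dose-response design.
#' @param replicates Replicate measurements (wells or screens).
#'
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$well_cv
sim_config <- function(seed = 1L,
                       well_cv = 0.05,
                       viability_noise_sd = 0.03,
                       expr_noise_sd = 0.5,
                       n_datasets = 4L,
                       genes = 200L,
                       samples = 4L,
                       doses = 8L,
                       replicates = 3L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  noise <- c(well_cv = well_cv, viability_noise_sd = viability_noise_sd,
             expr_noise_sd = expr_noise_sd)
  if (any(!is.finite(noise)) || any(noise < 0)) {
    stop("noise parameters must be finite and >= 0", call. = FALSE)
  }
  counts <- c(n_datasets = n_datasets, genes = genes, samples = samples,
              doses = doses, replicates = replicates)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    stop("count parameters must be integers >= 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 well_cv = well_cv,
                 viability_noise_sd = viability_noise_sd,
                 expr_noise_sd = expr_noise_sd,
                 n_datasets = as.integer(n_datasets),
                 genes = as.integer(genes),
                 samples = as.integer(samples),
                 doses = as.integer(doses),
                 replicates = as.integer(replicates)),
            class = "sim_config")
}

#' Drug-pair interaction specification
#'
#' Parameters of the constant-interaction generator for a two-drug
#' combination: each agent's median-effect slope and median-effect dose, and
#' the true combination index `kappa`. `kappa = 1` is Loewe additivity,
#' `kappa < 1` synergy, `kappa > 1` antagonism.
#'
#' @param m1,m2 Median-effect slopes (dimensionless, > 0).
#' @param Dm1,Dm2 Median-effect doses in nM (> 0); `Dm` is the dose giving
#'   50% effect, i.e. the IC50 under this model.
#' @param kappa True combination index (> 0).
#'
#' @return An object of class `interaction_spec`.
#' @export
#' @examples
#' interaction_spec(m1 = 1.3, Dm1 = 20, m2 = 1.5, Dm2 = 173, kappa = 0.5)
interaction_spec <- function(m1, Dm1, m2, Dm2, kappa = 1) {
  p <- c(m1 = m1, Dm1 = Dm1, m2 = m2, Dm2 = Dm2, kappa = kappa)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("m1, m2, Dm1, Dm2 and kappa must all be finite and > 0",
         call. = FALSE)
  }
  structure(list(m1 = m1, Dm1 = Dm1, m2 = m2, Dm2 = Dm2, kappa = kappa),
            class = "interaction_spec")
}
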