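#' Median-effect fraction affected
#'
#' The median-effect model of dose response: the fraction of cells affected
#' at dose `D` is `fa = (D/Dm)^m / (1 + (D/Dm)^m)`, where `Dm` is the dose
#' giving half-maximal effect (the IC50) and `m` the sigmoidicity slope.
#'
#' @param D Dose (nM), vectorized.
#' @param m Slope (> 0).
#' @param Dm Median-effect dose (nM, > 0).
#' @return Fraction affected in (0, 1).
#' @export
#' @examples
#' median_effect_fa(c(5, 20, 80), m = 1, Dm = 20)
median_effect_fa <- function(D, m, Dm) {
  if (!is.finite(m) || m <= 0 || !is.finite(Dm) || Dm <= 0) {
    stop("m and Dm must be > 0", call. = FALSE)
  }
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("doses must be > 0", call. = FALSE)
  }
  r <- (D / Dm)^m
  r / (1 + r)
}

#' Simulate single-agent viability from the median-effect model
#'
#' Generates an MTS-style viability table: at each dose the true viability
#' is `1 - fa(D)` under the median-effect equation, replicate measurements
#' receive additive Gaussian noise of sd `noise_sd` and are clipped to
#' `[0, 1.2]` (treated wells can read slightly above vehicle in real MTS
#' data). Vehicle (DMSO) replicates with true viability 1 are included so
#' that the analysis pipeline performs its own vehicle normalization.
#'
#' @param m,Dm Median-effect slope and dose (nM), both > 0.
#' @param doses Numeric vector of doses (nM, > 0).
#' @param reps Replicates per dose.
#' @param noise_sd Additive viability noise sd (fraction of vehicle).
#' @param seed Integer seed.
#' @param agent Agent name recorded in the table.
#' @param experiment_id Experiment label.
#' @return data.frame in the viability dialect: `experiment_id`, `agent1`,
#'   `dose1_nM`, `agent2`, `dose2_nM`, `replicate`, `signal`, `is_vehicle`.
#' @export
#' @examples
#' v <- gen_dose_response(m = 1, Dm = 20, doses = c(5, 20, 80),
#'                        reps = 3, noise_sd = 0, seed = 1)
#' subset(v, dose1_nM == 20 & !is_vehicle)$signal  # 0.5: the median-effect dose
gen_dose_response <- function(m, Dm, doses, reps = 3L, noise_sd = 0.03,
                              seed = 1L, agent = "drug",
                              experiment_id = "exp1") {
  if (!is.finite(m) || m <= 0 || !is.finite(Dm) || Dm <= 0) {
    stop("m and Dm must be > 0", call. = FALSE)
  }
  if (length(doses) < 1L || any(!is.finite(doses)) || any(doses <= 0)) {
    stop("doses must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  fa <- median_effect_fa(doses, m, Dm)
  true_v <- c(rep(1, reps), rep(1 - fa, each = reps))
  n <- length(true_v)
  signal <- pmin(pmax(true_v + stats::rnorm(n, 0, noise_sd), 0), 1.2)
  data.frame(
    experiment_id = experiment_id,
    agent1 = agent,
    dose1_nM = c(rep(0, reps), rep(doses, each = reps)),
    agent2 = NA_character_,
    dose2_nM = NA_real_,
    replicate = c(seq_len(reps), rep(seq_len(reps), length(doses))),
    signal = signal,
    is_vehicle = c(rep(TRUE, reps), rep(FALSE, n - reps)),
    stringsAsFactors = FALSE)
}

#' True fraction affected of a constant-interaction combination
#'
#' Under the constant combination-index deformation of Loewe additivity, the
#' effect of the dose pair `(D1, D2)` is the `fa` solving
#' `D1/Dx1(fa) + D2/Dx2(fa) = kappa`, where
#' `Dxi(fa) = Dmi * (fa/(1-fa))^(1/mi)` is agent i's single-agent dose for
#' effect `fa`. The left side decreases strictly from infinity to 0 as `fa`
#' runs over (0, 1), so a unique root always exists for a valid
#' specification; it is found by bisection to `|delta fa| < 1e-10`. With
#' `m1 = m2 = 1` the closed form `fa = R/(R + kappa)`,
#' `R = D1/Dm1 + D2/Dm2`, is used directly by the solver's callers as a
#' cross-check in tests.
#'
#' @param spec An [interaction_spec()].
#' @param D1,D2 Doses (nM, > 0), vectorized in parallel.
#' @return Fraction affected in (0, 1).
#' @export
#' @examples
#' sp <- interaction_spec(m1 = 1, Dm1 = 10, m2 = 1, Dm2 = 100, kappa = 1)
#' combination_fa(sp, 10, 100)  # 2/3
combination_fa <- function(spec, D1, D2) {
  stopifnot(inherits(spec, "interaction_spec"))
  if (any(!is.finite(c(D1, D2))) || any(c(D1, D2) <= 0)) {
    stop("doses must be > 0 componentwise", call. = FALSE)
  }
  ci_at <- function(fa, d1, d2) {
    d1 / (spec$Dm1 * (fa / (1 - fa))^(1 / spec$m1)) +
      d2 / (spec$Dm2 * (fa / (1 - fa))^(1 / spec$m2))
  }
  mapply(function(d1, d2) {
    lo <- 1e-12; hi <- 1 - 1e-12
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (ci_at(mid, d1, d2) > spec$kappa) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, D1, D2)
}

#' Simulate combination viability under a constant combination index
#'
#' Generates a combination viability table whose true effect at each dose
#' pair follows the constant-interaction model of [combination_fa()];
#' replicate viabilities receive additive Gaussian noise and clipping as in
#' [gen_dose_response()], and vehicle replicates are included.
#'
#' @param spec An [interaction_spec()].
#' @param dose_pairs Two-column matrix or data.frame of (D1, D2) in nM.
#' @param reps Replicates per pair.
#' @param noise_sd Additive viability noise sd.
#' @param seed Integer seed.
#' @param agents Character vector of length 2, agent names.
#' @param experiment_id Experiment label.
#' @return data.frame in the viability dialect (see [gen_dose_response()]).
#' @export
gen_combination <- function(spec, dose_pairs, reps = 3L, noise_sd = 0.03,
                            seed = 1L, agents = c("drug1", "drug2"),
                            experiment_id = "combo1") {
  stopifnot(inherits(spec, "interaction_spec"))
  dose_pairs <- as.matrix(dose_pairs)
  if (ncol(dose_pairs) != 2L) stop("dose_pairs must have two columns",
                                   call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  fa <- combination_fa(spec, dose_pairs[, 1], dose_pairs[, 2])
  true_v <- c(rep(1, reps), rep(1 - fa, each = reps))
  n <- length(true_v)
  signal <- pmin(pmax(true_v + stats::rnorm(n, 0, noise_sd), 0), 1.2)
  data.frame(
    experiment_id = experiment_id,
    agent1 = agents[1],
    dose1_nM = c(rep(0, reps), rep(dose_pairs[, 1], each = reps)),
    agent2 = agents[2],
    dose2_nM = c(rep(0, reps), rep(dose_pairs[, 2], each = reps)),
    replicate = c(seq_len(reps), rep(seq_len(reps), nrow(dose_pairs))),
    signal = signal,
    is_vehicle = c(rep(TRUE, reps), rep(FALSE, n - reps)),
    stringsAsFactors = FALSE)
}
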