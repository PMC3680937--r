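#' Fraction of cells affected relative to vehicle
#'
#' `fa = 1 - mean(treated)/mean(vehicle)`: replicates are averaged before
#' the ratio is taken. The result is clipped into `[eps, 1 - eps]` so that
#' the logit used by the median-effect regression stays finite; clipped
#' points are flagged and later excluded from fitting.
#'
#' @param treated Numeric vector of treated replicate signals (>= 1 value).
#' @param vehicle Numeric vector of vehicle replicate signals.
#' @param eps Clip bound (default 1e-4).
#' @return List with `fa`, `fu = 1 - fa`, and `clipped` (logical).
#' @export
#' @examples
#' fraction_affected(c(0.24, 0.26), c(0.98, 1.02))  # fa = 0.75
fraction_affected <- function(treated, vehicle, eps = 1e-4) {
  if (length(vehicle) < 1L || !is.finite(mean(vehicle)) || mean(vehicle) <= 0) {
    stop("vehicle mean must be > 0", call. = FALSE)
  }
  if (length(treated) < 1L) stop("no treated replicates", call. = FALSE)
  fa_raw <- 1 - mean(treated) / mean(vehicle)
  fa <- min(max(fa_raw, eps), 1 - eps)
  list(fa = fa, fu = 1 - fa, clipped = (fa != fa_raw))
}

#' Collapse a viability table into effect points
#'
#' Averages replicates per dose (or dose pair) and converts to fraction
#' affected against the table's own vehicle rows.
#'
#' @param viability Viability table in the dialect of
#'   [gen_dose_response()] / [gen_combination()].
#' @param eps Clip bound passed to [fraction_affected()].
#' @return data.frame with `dose1_nM`, `dose2_nM`, `fa`, `fu`, `clipped`,
#'   ordered by dose.
#' @export
effect_points <- function(viability, eps = 1e-4) {
  req <- c("dose1_nM", "signal", "is_vehicle")
  if (!all(req %in% names(viability))) {
    stop("viability table missing columns: ",
         paste(setdiff(req, names(viability)), collapse = ", "),
         call. = FALSE)
  }
  veh <- viability$signal[viability$is_vehicle]
  if (length(veh) == 0L) stop("no vehicle data in viability table",
                              call. = FALSE)
  trt <- viability[!viability$is_vehicle, , drop = FALSE]
  if (is.null(trt$dose2_nM)) trt$dose2_nM <- NA_real_
  key <- paste(trt$dose1_nM, trt$dose2_nM)
  out <- lapply(split(trt, key), function(g) {
    fp <- fraction_affected(g$signal, veh, eps = eps)
    data.frame(dose1_nM = g$dose1_nM[1], dose2_nM = g$dose2_nM[1],
               fa = fp$fa, fu = fp$fu, clipped = fp$clipped)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$dose1_nM, res$dose2_nM), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fit the median-effect model
#'
#' Linearizes the median-effect equation `fa/fu = (D/Dm)^m` and fits
#' ordinary least squares of `log10(fa/fu)` on `log10(D)`: the slope is
#' `m` and the intercept `-m * log10(Dm)`, so `Dm = 10^(-b0/m)`; the linear
#' correlation coefficient `r` of the plot is reported as the goodness of
#' fit. `Dm` is the dose of half-maximal effect and is reported as the
#' IC50. Points clipped at the fa bounds are excluded from the regression.
#'
#' The logit transform amplifies measurement noise without bound as fa
#' approaches 0 or 1, so effect levels outside `fa_range` (default
#' `[0.1, 0.9]`, the region the median-effect plot is considered reliable
#' in) are also excluded — unless that would leave fewer than two distinct
#' doses, in which case all unclipped points are used.
#'
#' @param points data.frame with columns `dose1_nM` (or `D`), `fa`, and
#'   optionally `clipped`; single-agent points only.
#' @param eps fa values within `eps` of 0 or 1 are treated as clipped.
#' @param fa_range Effect-level window used for fitting.
#' @return Object of class `median_effect_fit`: list with `m`, `Dm`, `r`,
#'   `n` (points used), `n_clipped` (excluded).
#' @export
#' @examples
#' pts <- data.frame(D = c(5, 20, 80), fa = c(0.2, 0.5, 0.8))
#' fit <- fit_median_effect(pts)
#' c(fit$m, fit$Dm, fit$r)  # 1, 20, 1
fit_median_effect <- function(points, eps = 1e-4, fa_range = c(0.1, 0.9)) {
  D <- if (!is.null(points$dose1_nM)) points$dose1_nM else points$D
  if (is.null(D)) stop("points must have a dose column (dose1_nM or D)",
                       call. = FALSE)
  fa <- points$fa
  clipped <- if (!is.null(points$clipped)) points$clipped else
    (fa <= eps | fa >= 1 - eps)
  keep <- !clipped & is.finite(D) & D > 0
  in_window <- keep & fa >= fa_range[1] & fa <= fa_range[2]
  if (length(unique(D[in_window])) >= 2L) keep <- in_window
  D <- D[keep]; fa <- fa[keep]
  if (length(unique(D)) < 2L) {
    stop("median-effect fit needs >= 2 distinct unclipped doses",
         call. = FALSE)
  }
  x <- log10(D)
  y <- log10(fa / (1 - fa))
  b <- stats::coef(stats::lm(y ~ x))
  m <- unname(b[2]); b0 <- unname(b[1])
  if (!is.finite(m) || m <= 0) {
    stop("fitted median-effect slope is not positive: no dose response",
         call. = FALSE)
  }
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  structure(list(m = m, Dm = 10^(-b0 / m), r = r,
                 n = length(D), n_clipped = sum(clipped)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median-effect fit: m = %.4g, Dm (IC50) = %.4g nM, r = %.4f (n = %d)\n",
              x$m, x$Dm, x$r, x$n))
  invisible(x)
}

#' Single-agent dose for a given effect level
#'
#' Inverts the fitted median-effect curve:
#' `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit A [fit_median_effect()] result (or any list with `m`, `Dm`).
#' @param fa Effect level strictly inside (0, 1), vectorized.
#' @return Dose in nM.
#' @export
dose_for_effect <- function(fit, fa) {
  if (any(!is.finite(fa)) || any(fa <= 0) || any(fa >= 1)) {
    stop("fa must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index for one dose pair
#'
#' `CI = D1/Dx1(fa) + D2/Dx2(fa)` evaluated at the combination's observed
#' fraction affected, with `Dxi` from each agent's single-agent
#' median-effect fit (the mutually-exclusive two-term form). CI below 1
#' indicates synergy, 1 additivity, above 1 antagonism; classification uses
#' an additivity band of half-width `delta` because an exact CI of 1 is
#' measure-zero on noisy data.
#'
#' @param fit1,fit2 Single-agent [fit_median_effect()] results.
#' @param D1,D2 Combination doses (nM).
#' @param fa Observed fraction affected of the combination, in (0, 1) and
#'   away from the clip bounds.
#' @param delta Additivity band half-width (default 0.05).
#' @param eps Clip bound; `fa` at or beyond the bounds is an error (CI is
#'   undefined there).
#' @return List with `D1`, `D2`, `fa`, `CI`, `class`.
#' @export
#' @examples
#' f1 <- fit_median_effect(data.frame(D = c(5, 10, 20), fa = c(1/3, 0.5, 2/3)))
#' f2 <- fit_median_effect(data.frame(D = c(50, 100, 200), fa = c(1/3, 0.5, 2/3)))
#' combination_index(f1, f2, D1 = 5, D2 = 50, fa = 0.5)$CI  # 1: additive
combination_index <- function(fit1, fit2, D1, D2, fa, delta = 0.05,
                              eps = 1e-4) {
  if (!is.finite(fa) || fa <= eps || fa >= 1 - eps) {
    stop("combination fa at clip bounds: CI undefined", call. = FALSE)
  }
  if (any(c(D1, D2) <= 0)) stop("combination doses must be > 0",
                                call. = FALSE)
  ci <- D1 / dose_for_effect(fit1, fa) + D2 / dose_for_effect(fit2, fa)
  cls <- if (ci < 1 - delta) "synergistic"
         else if (ci > 1 + delta) "antagonistic"
         else "additive"
  list(D1 = D1, D2 = D2, fa = fa, CI = ci, class = cls)
}

#' Fa-CI profile of a combination experiment
#'
#' Computes the combination index at every dose pair of a combination
#' viability table (or precomputed effect points) and summarizes: mean CI,
#' fraction of points with CI < 1, and an overall synergy flag raised when
#' every point is below 1.
#'
#' @param fit1,fit2 Single-agent median-effect fits.
#' @param combo Combination effect points (data.frame with `dose1_nM`,
#'   `dose2_nM`, `fa`; see [effect_points()]) or a raw combination
#'   viability table, which is collapsed first.
#' @param delta,eps Passed to [combination_index()].
#' @return List with `points` (data.frame `D1`, `D2`, `fa`, `CI`, `class`),
#'   `mean_CI`, `frac_below_1`, `all_synergistic`.
#' @export
fa_ci_profile <- function(fit1, fit2, combo, delta = 0.05, eps = 1e-4) {
  if (!is.null(combo$signal)) combo <- effect_points(combo, eps = eps)
  combo <- combo[!(combo$fa <= eps | combo$fa >= 1 - eps), , drop = FALSE]
  if (nrow(combo) == 0L) {
    stop("no usable combination points (all clipped or empty)",
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(combo)), function(i) {
    res <- combination_index(fit1, fit2, combo$dose1_nM[i],
                             combo$dose2_nM[i], combo$fa[i],
                             delta = delta, eps = eps)
    data.frame(D1 = res$D1, D2 = res$D2, fa = res$fa, CI = res$CI,
               class = res$class, stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, rows)
  list(points = pts,
       mean_CI = mean(pts$CI),
       frac_below_1 = mean(pts$CI < 1),
       all_synergistic = all(pts$CI < 1))
}
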