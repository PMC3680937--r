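# Heavier seeded property suites for the generator / analysis round trips.

test_that("noise-free dose-response fits recover m and Dm to 1e-8", {
  set.seed(31)
  for (i in 1:20) {
    m <- runif(1, 0.6, 2.5)
    Dm <- runif(1, 2, 300)
    doses <- Dm * 10^seq(-1.5, 1.5, length.out = 7)
    fit <- fit_noise_free(m, Dm, doses)
    expect_lt(abs(fit$m - m) / m, 1e-8)
    expect_lt(abs(fit$Dm - Dm) / Dm, 1e-8)
    expect_equal(fit$r, 1, tolerance = 1e-10)
  }
})

test_that("fitted effect curves are strictly increasing in dose", {
  fit <- fit_noise_free(1.7, 40, c(5, 10, 40, 160, 640))
  D <- 10^seq(-2, 4, length.out = 200)
  fa <- median_effect_fa(D, fit$m, fit$Dm)
  expect_true(all(diff(fa) > 0))
})

test_that("noisy dose-response fits recover Dm with < 10% median error", {
  Dm <- 20; m <- 1.3
  doses <- Dm * 10^seq(-1.5, 1.5, length.out = 8)
  errs <- vapply(1:100, function(s) {
    v <- gen_dose_response(m, Dm, doses, reps = 3, noise_sd = 0.03,
                           seed = 1000 + s)
    abs(fit_median_effect(effect_points(v))$Dm - Dm) / Dm
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("CI round-trips equal kappa across slopes, potencies and pairs", {
  set.seed(77)
  for (i in 1:8) {
    m1 <- runif(1, 0.7, 2.2); m2 <- runif(1, 0.7, 2.2)
    Dm1 <- runif(1, 5, 60); Dm2 <- runif(1, 40, 400)
    kap <- sample(c(0.3, 0.7, 1, 1.8), 1)
    sp <- interaction_spec(m1, Dm1, m2, Dm2, kappa = kap)
    f1 <- fit_noise_free(m1, Dm1, Dm1 * 10^seq(-1.2, 1.2, length.out = 6))
    f2 <- fit_noise_free(m2, Dm2, Dm2 * 10^seq(-1.2, 1.2, length.out = 6))
    pairs <- cbind(Dm1 * 2^(-1:2), Dm2 * 2^(-1:2))
    prof <- fa_ci_profile(f1, f2, gen_combination(sp, pairs, reps = 2,
                                                  noise_sd = 0, seed = i))
    expect_equal(prof$points$CI, rep(kap, nrow(pairs)), tolerance = 1e-6)
  }
})

test_that("planted screen hits are called exactly, with rare false positives", {
  planted <- sprintf("SG%03d", c(3, 17, 30, 55, 77, 101))
  nulls <- setdiff(sprintf("SG%03d", 1:108), planted)
  exact <- 0L; fp <- 0L
  for (s in 1:100) {
    pl <- gen_screen(sim_config(seed = 5000 + s, well_cv = 0.05,
                                replicates = 2),
                     108, hit_genes = planted, inhibition = 0.5)
    ht <- hit_table(plate_zscores(normalize_to_nts(pl)))
    hits <- call_hits(ht$z, ht$screens$cell_line, tau = -1.4)$SIMLINE
    if (setequal(hits, planted)) exact <- exact + 1L
    fp <- fp + length(intersect(hits, nulls))
  }
  expect_gte(exact, 95)
  expect_lt(fp / (100 * length(nulls)), 0.01)
})

test_that("tumor-like samples co-cluster under a planted signature but not under the null", {
  co_rate <- function(effect, n_seeds, base_seed) {
    hits <- 0L
    for (s in seq_len(n_seeds)) {
      coll <- gen_expression_collection(
        sim_config(seed = base_seed + s, samples = 3, n_datasets = 3),
        n_signature = 60, n_background = 90, effect = effect)
      res <- suppressMessages(suppressWarnings(
        signature_cluster_pipeline(coll$datasets, coll$homology,
                                   coll$signature)))
      tum <- colnames(res$matrix$values)[res$matrix$group == "tumor_like"]
      if (co_cluster(res$tree, 2, tum)$co_clustered) hits <- hits + 1L
    }
    hits / n_seeds
  }
  expect_gte(co_rate(2.0, 30, 800), 0.95)
  # null: co-clustering of the 9 tumor-like samples at k = 2 should occur
  # at no more than chance rate (binomial check, far below the planted rate)
  null_rate <- co_rate(0, 30, 900)
  expect_lt(null_rate, 0.5)
})
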