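test_that("fraction affected averages replicates and clips at the bounds", {
  expect_equal(fraction_affected(c(0.24, 0.26), c(0.98, 1.02))$fa, 0.75)
  same <- fraction_affected(1, 1)
  expect_equal(same$fa, 1e-4)
  expect_true(same$clipped)
  over <- fraction_affected(1.1, 1)   # treated above vehicle
  expect_equal(over$fa, 1e-4)
  expect_true(over$clipped)
  expect_error(fraction_affected(0.5, numeric()), "vehicle")
  expect_error(fraction_affected(0.5, c(-1, 1)), "vehicle mean")
})

test_that("the median-effect fit linearizes exact points perfectly", {
  fit <- fit_median_effect(data.frame(D = c(5, 20, 80),
                                      fa = c(0.2, 0.5, 0.8)))
  expect_equal(fit$m, 1, tolerance = 1e-12)
  expect_equal(fit$Dm, 20, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  # fitted curve passes through fa = 0.5 at Dm by definition
  expect_equal(median_effect_fa(fit$Dm, fit$m, fit$Dm), 0.5)
  expect_error(fit_median_effect(data.frame(D = 5, fa = 0.2)),
               "2 distinct")
  expect_error(fit_median_effect(data.frame(D = c(5, 20),
                                            fa = c(1e-5, 1e-5))),
               "2 distinct")
})

test_that("dose_for_effect inverts the fitted curve", {
  fit <- list(m = 1, Dm = 20)
  expect_equal(dose_for_effect(fit, 0.5), 20)
  expect_equal(dose_for_effect(fit, 0.8), 80)
  expect_equal(dose_for_effect(list(m = 2, Dm = 50), 0.8), 100)
  expect_error(dose_for_effect(fit, 1), "inside")
})

test_that("the combination index and its classes follow CI vs 1", {
  f1 <- fit_median_effect(data.frame(D = c(5, 10, 20),
                                     fa = c(1 / 3, 0.5, 2 / 3)))
  f2 <- fit_median_effect(data.frame(D = c(50, 100, 200),
                                     fa = c(1 / 3, 0.5, 2 / 3)))
  add <- combination_index(f1, f2, 5, 50, fa = 0.5)
  expect_equal(add$CI, 1, tolerance = 1e-10)
  expect_equal(add$class, "additive")
  syn <- combination_index(f1, f2, 2, 20, fa = 0.5)
  expect_equal(syn$CI, 0.4, tolerance = 1e-10)
  expect_equal(syn$class, "synergistic")
  ant <- combination_index(f1, f2, 20, 200, fa = 0.5)
  expect_equal(ant$CI, 4, tolerance = 1e-10)
  expect_equal(ant$class, "antagonistic")
  expect_error(combination_index(f1, f2, 5, 50, fa = 1e-5), "clip bounds")
})

test_that("noise-free constant-CI simulations round-trip through the CI profile", {
  doses1 <- 10^seq(-1, 3, length.out = 8)
  doses2 <- 10^seq(0, 4, length.out = 8)
  f1 <- fit_noise_free(1.3, 20, doses1)
  f2 <- fit_noise_free(1.5, 173, doses2)
  pairs <- cbind(20 * 2^(-2:3), 173 * 2^(-2:3))
  for (kap in c(0.5, 1)) {
    sp <- interaction_spec(1.3, 20, 1.5, 173, kappa = kap)
    cb <- gen_combination(sp, pairs, reps = 2, noise_sd = 0, seed = 1)
    prof <- fa_ci_profile(f1, f2, cb)
    expect_equal(prof$points$CI, rep(kap, nrow(pairs)), tolerance = 1e-6)
    expect_equal(prof$mean_CI, kap, tolerance = 1e-6)
    if (kap < 1) expect_true(prof$all_synergistic)
  }
  expect_error(fa_ci_profile(f1, f2, data.frame(dose1_nM = 1, dose2_nM = 1,
                                                fa = 1e-5)),
               "no usable")
})

test_that("significance tiers follow the lettered p-value ladder", {
  # oracle p-value computed directly with the same classical t-test
  tier_of <- function(p) {
    if (p <= 5e-4) "D" else if (p <= 1e-3) "C"
    else if (p <= 5e-3) "B" else if (p <= 1e-2) "A" else "none"
  }
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4, mean = runif(1, 0, 4))
    res <- significance_tiers(a, b)
    p_ref <- stats::t.test(a, b, var.equal = TRUE)$p.value
    expect_equal(res$p, p_ref)
    expect_equal(res$tier, tier_of(p_ref))
  }
  expect_equal(significance_tiers(c(1, 2, 3), c(1, 2, 3))$tier, "none")
  expect_error(significance_tiers(1, c(1, 2)), ">= 2")
})

test_that("tumor volume follows length x width^2 / 2", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(2, 2), 4)
  expect_equal(tumor_volume(c(10, 2), c(5, 2)), c(125, 4))
  expect_error(tumor_volume(5, 0), "> 0")
})

test_that("group association and Pearson correlation behave classically", {
  g <- rep(c("a", "b"), each = 3)
  res <- group_association(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_association(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_association(c(-1, 0, 1, 0), c(0, -1, 0, 1))$r, 0)
  expect_error(pearson_association(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(group_association(1:4, rep("a", 4)), "two groups")
})
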