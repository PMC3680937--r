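mk_plate <- function(lib_vals, nts = c(0.8, 0.8, 0.8),
                     genes = sprintf("G%02d", seq_along(lib_vals))) {
  data.frame(
    plate_id = "P01", screen_id = "L_s1", cell_line = "L",
    well = c(sprintf("A%02d", 2:(1 + length(nts))),
             plate_wells(interior = TRUE)[seq_along(lib_vals)]),
    content_type = c(rep("NTS", length(nts)),
                     rep("library", length(lib_vals))),
    gene_id = c(rep(NA, length(nts)), genes),
    absorbance = c(nts, lib_vals), stringsAsFactors = FALSE)
}

test_that("NTS normalization divides by the plate's NTS mean", {
  pl <- mk_plate(c(0.4, 0.8, 1.2))
  norm <- normalize_to_nts(pl)
  expect_equal(sort(norm$viability), c(0.5, 1.0, 1.5))
  no_nts <- pl[pl$content_type != "NTS", ]
  expect_error(normalize_to_nts(no_nts), "no NTS wells")
  zero <- mk_plate(c(0.4), nts = c(0, 0, 0))
  expect_error(normalize_to_nts(zero), "non-positive NTS mean")
})

test_that("plate z-scores use the library mean and sample sd", {
  # library values (0.4, 0.8, 1.0, 1.0, 1.2, 1.6): mean 1, sample sd 0.4
  pl <- mk_plate(0.8 * c(0.4, 0.8, 1.0, 1.0, 1.2, 1.6))
  z <- plate_zscores(normalize_to_nts(pl))
  expect_equal(z$z[which.min(z$viability)], -1.5)
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$z), 1, tolerance = 1e-12)
  flat <- mk_plate(rep(0.8, 5))
  expect_error(plate_zscores(normalize_to_nts(flat)), "zero spread")
  tiny <- mk_plate(c(0.4, 0.8))
  expect_error(plate_zscores(normalize_to_nts(tiny)), "fewer than 3")
})

test_that("z-scores are invariant to global absorbance rescaling", {
  pl <- gen_screen(sim_config(seed = 2, replicates = 2), 60,
                   hit_genes = c("SG003"), inhibition = 0.5)
  z1 <- plate_zscores(normalize_to_nts(pl))
  pl2 <- pl
  pl2$absorbance <- pl2$absorbance * 7.3
  z2 <- plate_zscores(normalize_to_nts(pl2))
  expect_equal(z1$z, z2$z, tolerance = 1e-12)
})

test_that("the published z-matrix yields the known hit and selectivity calls", {
  tab <- tnbc_screen_zscores()
  hits <- call_hits(tab$z, tab$screens$cell_line, tau = -1.4)
  expect_setequal(hits$MB231,
                  c("ANLN", "CHEK1", "KIF11", "RRM1", "RRM2", "TPX2"))
  expect_setequal(hits$MCF10A, c("ANLN", "KIF11", "TPX2"))
  calls <- classify_selectivity(hits, tumor_lines = c("MB231", "Hs578T"),
                                control_line = "MCF10A")
  expect_setequal(calls$gene_id[calls$call == "selective"],
                  c("CHEK1", "RRM1", "RRM2"))
  expect_setequal(calls$gene_id[calls$call == "nonselective"],
                  c("ANLN", "KIF11", "TPX2"))
  # a stringent threshold yields no hits anywhere
  none <- call_hits(tab$z, tab$screens$cell_line, tau = -5)
  expect_true(all(lengths(none) == 0))
  expect_equal(nrow(classify_selectivity(none, c("MB231", "Hs578T"),
                                         "MCF10A")), 0)
})

test_that("selectivity edge cases resolve to non_hit", {
  hits <- list(T1 = character(), T2 = "gA", C = "gB")
  calls <- classify_selectivity(hits, c("T1", "T2"), "C")
  expect_true(all(calls$call == "non_hit"))   # gA not in all tumor lines,
                                              # gB only in control
  expect_error(classify_selectivity(hits, c("T1", "T9"), "C"), "missing")
  expect_error(classify_selectivity(hits, "T1", "X"), "control line")
})

test_that("deconvolution counts active oligos against the threshold", {
  ref <- 1.0
  r <- deconvolution_summary(c(0.50, 0.60, 0.70, 0.95), ref,
                             activity_threshold = 70)
  expect_equal(r$percent_growth, c(50, 60, 70, 95))
  expect_equal(r$n_active, 3)
  expect_true(r$confirmed)
  expect_equal(deconvolution_summary(rep(ref, 4), ref)$percent_growth,
               rep(100, 4))
  expect_false(deconvolution_summary(c(0.5, 0.9, 0.9, 0.95), ref)$confirmed)
  expect_error(deconvolution_summary(c(1, 1, 1), 1), "exactly 4")
  expect_error(deconvolution_summary(rep(1, 4), 0), "> 0")
})

test_that("planted screen hits are recovered end to end", {
  planted <- sprintf("SG%03d", c(5, 23, 41, 67, 88, 102))
  pl <- gen_screen(sim_config(seed = 17, well_cv = 0.05, replicates = 2),
                   108, hit_genes = planted, inhibition = 0.5)
  ht <- hit_table(plate_zscores(normalize_to_nts(pl)))
  hits <- call_hits(ht$z, ht$screens$cell_line, tau = -1.4)
  expect_setequal(hits$SIMLINE, planted)
})
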