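# Shared helpers: independent clustering oracle and partition comparison.

# TRUE iff two flat clusterings induce the same partition (labels may
# differ by permutation).
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(cbind(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Library-route oracle: stats::hclust complete linkage on the same
# distances. Agreement is checked via merge heights and the partition at
# every k (merge order within ties may differ in representation only; the
# random instances used are tie-free with probability 1).
expect_matches_hclust_oracle <- function(m) {
  d <- uncentered_corr_dist(m)
  ours <- cluster_complete(m)
  ref <- stats::hclust(d, method = "complete")
  expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-12)
  for (k in seq_len(ncol(m))) {
    expect_true(same_partition(stats::cutree(ours, k),
                               stats::cutree(ref, k)))
  }
}

# Median-effect fit from a noise-free simulated curve.
fit_noise_free <- function(m, Dm, doses) {
  v <- gen_dose_response(m = m, Dm = Dm, doses = doses, reps = 2,
                         noise_sd = 0, seed = 1)
  fit_median_effect(effect_points(v))
}
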