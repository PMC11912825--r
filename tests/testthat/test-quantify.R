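toy_table <- function() {
  counts <- matrix(c(100L, 50L, 800L, 50L,
                     200L, 100L, 600L, 100L), ncol = 2,
                   dimnames = list(c("asv1", "asv2", "asv3", "asv4"),
                                   c("s1", "s2")))
  count_table(counts)
}

test_that("count_table validates structure and integer counts", {
  tab <- toy_table()
  expect_s3_class(tab, "count_table")
  expect_error(count_table(matrix(1:4, 2)), "rownames")
  m <- matrix(c(1.5, 2, 3, 4), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(count_table(m), "non-negative integers")
})

test_that("feature assignment: exact, near-identical, dissimilar and ambiguous", {
  set.seed(31)
  mimic_amp <- random_seq(250)
  near <- mimic_amp
  substr(near, 100, 100) <- if (substr(near, 100, 100) == "A") "C" else "A"
  counts <- matrix(c(500L, 300L, 700L), ncol = 1,
                   dimnames = list(c("asv1", "asv2", "asv3"), "s1"))
  tab <- count_table(counts, feature_seqs = c(
    asv1 = mimic_amp, asv2 = near, asv3 = random_seq(250)))
  res <- assign_features(tab, c(mimicA = mimic_amp))
  expect_identical(unname(res$feature_map[c("asv1", "asv2")]),
                   c("mimicA", "mimicA"))
  expect_identical(unname(res$feature_map["asv3"]), "environmental")
  # multiple matching features are summed
  expect_identical(res$mimic_counts["mimicA", "s1"], 800L)
  expect_identical(unname(res$env_counts["s1"]), 700)
  # partition invariant: mimic + environmental = total, exactly
  expect_identical(sum(res$mimic_counts) + sum(res$env_counts),
                   sum(counts) + 0)
  # a feature matching two panel members violates the panel design
  expect_error(assign_features(tab, c(mimicA = mimic_amp, mimicB = mimic_amp)),
               "multiple mimics")
})

test_that("rarefaction preserves totals, proportions and determinism", {
  set.seed(32)
  counts <- matrix(as.integer(rmultinom(2, 2e5, prob = runif(40))), ncol = 2,
                   dimnames = list(sprintf("f%02d", 1:40), c("s1", "s2")))
  tab <- count_table(counts)
  sub <- rarefy_counts(tab, depth = 4e4, seed = 9)
  expect_true(all(colSums(sub$counts) == 4e4))
  expect_identical(rarefy_counts(tab, depth = 4e4, seed = 9)$counts,
                   sub$counts)
  # depth equal to the column sum returns the column unchanged
  full <- rarefy_counts(tab, depth = min(colSums(counts)), seed = 1)
  expect_true(all(colSums(full$counts) == min(colSums(counts))))
  expect_error(rarefy_counts(tab, depth = 1e9, seed = 1), "exceeds")
  # hypergeometric expectation: mean over replicates ~ depth * proportion
  reps <- vapply(1:200, function(i) {
    rarefy_counts(tab, depth = 4e4, seed = i)$counts[, 1]
  }, numeric(40))
  expected <- 4e4 * counts[, 1] / sum(counts[, 1])
  mc_sd <- sqrt(4e4 * counts[, 1] / sum(counts[, 1])) / sqrt(200) + 1e-9
  expect_true(all(abs(rowMeans(reps) - expected) < 6 * mc_sd))
})

test_that("ALR transform is exact and strict about zeros", {
  expect_identical(alr_transform(1000, 10), 2)
  expect_identical(alr_transform(50, 50), 0)
  expect_error(alr_transform(100, 0), "insufficient spike-in reads")
  expect_identical(alr_transform(100, 0, pseudocount = 0.5),
                   log10(100.5 / 0.5))
  # 10-fold spike difference, identical environmental pool: difference of 1
  expect_identical(alr_transform(50000, 500) - alr_transform(50000, 5000), 1)
})

test_that("load estimation arithmetic and QC exclusion", {
  counts <- matrix(c(500L, 5000L, 5L, 3000L), ncol = 2,
                   dimnames = list(c("mimic1", "env1"), c("s1", "s2")))
  tab <- count_table(counts)
  assign <- assignment_from_names(tab, "mimic1")
  spike <- spike_config(data.frame(
    sample = c("s1", "s2"), mimic = "mimic1", copies = 1e4,
    sample_amount = 50, amount_unit = "mg", amount_basis = "extraction"))
  loads <- estimate_load(assign, spike, reference = "mimic1")
  expect_equal(loads$absolute_load[1], 5000 / 500 * 1e4)  # 1e5 copies
  expect_equal(loads$normalized_load[1], 1e5 / 50)        # 2e3 per mg
  # sample with 5 mimic reads is excluded, not imputed
  expect_identical(loads$flag[2], "low_spike_reads")
  expect_true(is.na(loads$absolute_load[2]))
  # aggregate reference equals single mimic when only one is spiked
  agg <- estimate_load(assign, spike, reference = "aggregate")
  expect_equal(agg$absolute_load[1], loads$absolute_load[1])
})

test_that("differential load is antisymmetric and copies-aware", {
  counts <- matrix(c(1000L, 20000L, 1000L, 200L), ncol = 2,
                   dimnames = list(c("mimic1", "env1"), c("a", "b")))
  assign <- assignment_from_names(count_table(counts), "mimic1")
  spike <- spike_config(data.frame(
    sample = c("a", "b"), mimic = "mimic1", copies = c(1e4, 1e4),
    sample_amount = 1, amount_unit = "rxn", amount_basis = "pcr"))
  loads <- estimate_load(assign, spike, reference = "mimic1",
                         min_mimic_reads = 50)
  d <- differential_load(loads)
  ab <- d$delta_log10[d$sample_1 == "a" & d$sample_2 == "b"]
  ba <- d$delta_log10[d$sample_1 == "b" & d$sample_2 == "a"]
  expect_identical(ab, -ba)
  expect_equal(ab, 2)  # 100-fold environmental difference
  # with a 10-fold spike difference and identical counts, delta reflects it
  spike2 <- spike_config(data.frame(
    sample = c("a", "b"), mimic = "mimic1", copies = c(1e5, 1e4),
    sample_amount = 1, amount_unit = "rxn", amount_basis = "pcr"))
  loads2 <- estimate_load(assign, spike2, reference = "mimic1")
  d2 <- differential_load(loads2)
  ab2 <- d2$delta_log10[d2$sample_1 == "a" & d2$sample_2 == "b"]
  expect_equal(ab2, 2 + 1)
})

test_that("gmAFD matches its closed form and invariants", {
  expect_identical(gmafd(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(gmafd(c(2, 0.5), c(1, 1)), 2)
  expect_equal(gmafd(c(1.2, 1 / 1.5, 3), c(1, 1, 1)),
               exp((log(1.2) + log(1.5) + log(3)) / 3))
  # symmetry in (measured, expected)
  set.seed(33)
  m <- runif(10, 0.5, 2)
  e <- runif(10, 0.5, 2)
  expect_equal(gmafd(m, e), gmafd(e, m))
  # log10 and ln formulations agree
  expect_equal(gmafd(m, e), 10^mean(abs(log10(m / e))))
  expect_error(gmafd(c(1, -1), c(1, 1)), "positive")
})

test_that("BF ratio: equality, cancellation and zero handling", {
  mk_load <- function(sample, env, mimic, copies) {
    counts <- matrix(c(mimic, env), ncol = 1,
                     dimnames = list(c("cross", "env1"), sample))
    assign <- assignment_from_names(count_table(counts), "cross")
    spike <- spike_config(data.frame(
      sample = sample, mimic = "cross", copies = copies, sample_amount = 1,
      amount_unit = "rxn", amount_basis = "pcr"))
    estimate_load(assign, spike, reference = "cross")
  }
  b <- mk_load("s1", 8000L, 400L, 1e4)
  f <- mk_load("s1", 2000L, 400L, 1e4)
  expect_equal(bf_ratio(b, f), 4)
  expect_equal(bf_ratio(b, b), 1)
  # algebraic cancellation: same ratio whatever the (shared) spike copies
  b2 <- mk_load("s1", 8000L, 400L, 7e7)
  f2 <- mk_load("s1", 2000L, 400L, 7e7)
  expect_equal(bf_ratio(b2, f2), 4)
  expect_error(bf_ratio(b, mk_load("s2", 2000L, 400L, 1e4)), "same sample")
})
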