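test_that("simulated counts are deterministic and conserve ground truth", {
  sc <- sim_scenario(n_env_taxa = 20, mimic_copies = c(m1 = 5e3, m2 = 5e3),
                     depth = 5e4, n_samples = 3, seed = 51)
  sim <- simulate_counts(sc)
  sim2 <- simulate_counts(sc)
  expect_identical(sim$table$counts, sim2$table$counts)
  expect_identical(sim$truth, sim2$truth)
  # truth reproduces scenario parameters exactly
  expect_equal(sim$truth$spike_copies, rep(1e4, 3))
  expect_equal(sim$truth$env_load, rep(sum(sim$env_copies), 3))
  expect_true(all(colSums(sim$table$counts) == 5e4))
})

test_that("unbiased proportions converge to truth at high depth", {
  sc <- sim_scenario(n_env_taxa = 30, mimic_copies = c(m1 = 2e4),
                     depth = 1e6, n_samples = 1, bias_sdlog = 0, seed = 52)
  sim <- simulate_counts(sc)
  copies <- c(sim$env_copies, m1 = 2e4)
  p_true <- copies / sum(copies)
  p_obs <- sim$table$counts[, 1] / 1e6
  expect_true(all(abs(p_obs - p_true) < 0.01))
})

test_that("equimolar mimic pool is detected near-uniformly", {
  copies <- setNames(rep(1e4, 12), sprintf("mimic%02d", 1:12))
  sc <- sim_scenario(n_env_taxa = 1, env_meanlog = log(1e-6),
                     mimic_copies = copies, depth = 1.2e5, n_samples = 1,
                     bias_sdlog = 0, seed = 53)
  sim <- simulate_counts(sc)
  frac <- sim$table$counts[names(copies), 1] / sum(sim$table$counts[names(copies), 1])
  # binomial SD at this depth: sqrt(p(1-p)/N) ~ 8e-4; allow 5 sigma
  expect_true(all(abs(frac - 1 / 12) < 5 * sqrt((1 / 12) * (11 / 12) / 1.2e5)))
})

test_that("dilution series yields ALR slope -1 and exact noiseless differences", {
  base <- sim_scenario(mimic_copies = c(m1 = 1, m2 = 1), depth = 2e5,
                       seed = 54)
  sim <- simulate_dilution_series(base, levels = c(1e3, 1e4, 1e5, 1e6))
  assign <- assignment_from_names(sim$table, c("m1", "m2"))
  loads <- estimate_load(assign, sim$spike)
  fit <- lm(loads$alr ~ log10(loads$copies_added))
  expect_lt(abs(coef(fit)[2] - (-1)), 0.05)
  # two-level series: ALR difference equals the log10 level ratio
  sim2 <- simulate_dilution_series(base, levels = c(1e4, 1e5))
  a2 <- assignment_from_names(sim2$table, c("m1", "m2"))
  l2 <- estimate_load(a2, sim2$spike)
  expect_equal(l2$alr[1] - l2$alr[2], 1, tolerance = 0.1)
  # closed-form check on noiseless expected counts: slope is exactly -1
  env <- 1.6e5
  levels <- c(1e3, 1e4, 1e5, 1e6)
  alr_exact <- log10(env / levels)
  expect_equal(unname(coef(lm(alr_exact ~ log10(levels)))[2]), -1)
})

test_that("staggered mix simulation supports curve fitting end to end", {
  copies <- setNames(200 * 2^(0:7), sprintf("m%d", 1:8))
  sim <- simulate_staggered_mix(copies, depth = 1e5, seed = 55)
  expect_identical(sim$table$counts,
                   simulate_staggered_mix(copies, depth = 1e5, seed = 55)$table$counts)
  fit <- staggered_curve(sim$table$counts[, 1], sim$copies)
  expect_identical(fit$flag, "")
  expect_gt(fit$slope, 0.9)
  expect_lt(fit$slope, 1.1)
})

test_that("end-to-end differential-load recovery improves with depth", {
  gm <- vapply(c(1e3, 1e4, 1e5), function(depth) {
    base <- sim_scenario(n_env_taxa = 40, mimic_copies = c(m1 = 1, m2 = 1),
                         depth = depth, seed = 56)
    sim <- simulate_dilution_series(base, levels = c(1e4, 1e5, 1e6))
    assign <- assignment_from_names(sim$table, c("m1", "m2"))
    loads <- estimate_load(assign, sim$spike, min_mimic_reads = 5)
    d <- differential_load(loads)
    keep <- d$sample_1 < d$sample_2
    expected <- rep(1, sum(keep))  # equal env pool: zero load difference,
    # but ALR differences recover the spike ratios; compare fold scale
    alr_d <- abs(loads$alr[match(d$sample_1[keep], loads$sample)] -
                 loads$alr[match(d$sample_2[keep], loads$sample)])
    true_d <- abs(log10(loads$copies_added[match(d$sample_1[keep], loads$sample)] /
                        loads$copies_added[match(d$sample_2[keep], loads$sample)]))
    gmafd(10^alr_d, 10^true_d)
  }, numeric(1))
  expect_lt(gm[3], 1.1)
  expect_true(gm[3] <= gm[1] + 0.02)  # monotone improvement (small slack)
})

test_that("BF series recovers true ratios on the log scale", {
  ratios <- c(40, 10, 2.5, 1, 0.4, 0.1, 0.025)
  sim <- simulate_bf_series(ratios, depth = 1e5, seed = 57)
  bl <- estimate_load(sim$bacterial$assign, sim$bacterial$spike,
                      reference = "crossmimic")
  fl <- estimate_load(sim$fungal$assign, sim$fungal$spike,
                      reference = "crossmimic")
  measured <- vapply(seq_along(ratios), function(i) {
    bf_ratio(bl[i, ], fl[i, ])
  }, numeric(1))
  expect_gt(cor(log10(measured), log10(ratios)), 0.99)
})
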