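#' Simulation scenario for spike-in amplicon experiments
#'
#' Describes a synthetic experiment with known ground truth: an
#' environmental taxon pool with lognormal copy numbers, a mimic spike-in
#' panel, per-feature amplification-efficiency bias (lognormal, drawn once
#' and held constant across samples -- the mechanism that makes spike-in
#' bias cancel in differential analyses), and multinomial read sampling at
#' fixed depth.
#'
#' @param n_env_taxa number of environmental taxa (default 50).
#' @param env_meanlog,env_sdlog lognormal parameters of environmental copy
#'   numbers (defaults `log(2000)` and 1, giving a pool of roughly 1.6e5
#'   total copies).
#' @param mimic_copies spike copies: named vector (same for every sample) or
#'   mimics x samples matrix.
#' @param depth reads per sample.
#' @param n_samples number of samples (inferred from `mimic_copies` when it
#'   is a matrix).
#' @param env_scale per-sample multiplier on the environmental pool
#'   (length `n_samples`, default all 1: a fixed pool).
#' @param bias_sdlog sd(log) of per-feature efficiency bias (default 0.5;
#'   0 disables bias).
#' @param seed integer seed.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(n_env_taxa = 50L,
                         env_meanlog = log(2000), env_sdlog = 1,
                         mimic_copies = c(mimic1 = 1e4),
                         depth = 2e5, n_samples = NULL, env_scale = NULL,
                         bias_sdlog = 0.5, seed = 1L) {
  if (is.matrix(mimic_copies)) {
    stopifnot(!is.null(rownames(mimic_copies)))
    if (is.null(n_samples)) n_samples <- ncol(mimic_copies)
    stopifnot(ncol(mimic_copies) == n_samples)
  } else {
    stopifnot(!is.null(names(mimic_copies)))
    if (is.null(n_samples)) n_samples <- 1L
    mimic_copies <- matrix(rep(mimic_copies, n_samples),
                           ncol = n_samples,
                           dimnames = list(names(mimic_copies), NULL))
  }
  if (is.null(colnames(mimic_copies))) {
    colnames(mimic_copies) <- sprintf("sample%02d", seq_len(n_samples))
  }
  if (is.null(env_scale)) env_scale <- rep(1, n_samples)
  stopifnot(length(env_scale) == n_samples, all(env_scale > 0),
            all(mimic_copies > 0), n_env_taxa >= 1, depth >= 1,
            env_sdlog >= 0, bias_sdlog >= 0)
  structure(list(n_env_taxa = as.integer(n_env_taxa),
                 env_meanlog = env_meanlog, env_sdlog = env_sdlog,
                 mimic_copies = mimic_copies, depth = depth,
                 n_samples = as.integer(n_samples), env_scale = env_scale,
                 bias_sdlog = bias_sdlog, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a spiked ASV count table with ground truth
#'
#' Draws, per sample, multinomial read counts with probabilities
#' proportional to copy number times per-feature efficiency bias. Returns
#' the count table together with the ground truth needed to score any
#' downstream estimate.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `table` (a [count_table()]; mimic features carry their
#'   mimic id as feature id), `truth` (data.frame: `sample`, `env_load`,
#'   `spike_copies`, `expected_alr`), `env_copies`, `bias` and `spike` (a
#'   ready-made [spike_config()], amount 1 per PCR).
#' @export
simulate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  withr::with_seed(sc$seed, {
    env_ids <- sprintf("env%03d", seq_len(sc$n_env_taxa))
    mimic_ids <- rownames(sc$mimic_copies)
    env_copies <- setNames(rlnorm(sc$n_env_taxa, sc$env_meanlog, sc$env_sdlog),
                           env_ids)
    bias <- setNames(rlnorm(sc$n_env_taxa + length(mimic_ids), 0, sc$bias_sdlog),
                     c(env_ids, mimic_ids))
    counts <- matrix(0L, nrow = sc$n_env_taxa + length(mimic_ids),
                     ncol = sc$n_samples,
                     dimnames = list(c(env_ids, mimic_ids),
                                     colnames(sc$mimic_copies)))
    for (j in seq_len(sc$n_samples)) {
      copies <- c(env_copies * sc$env_scale[j], sc$mimic_copies[, j])
      probs <- copies * bias
      counts[, j] <- rmultinom(1, size = sc$depth, prob = probs / sum(probs))
    }
    truth <- data.frame(
      sample = colnames(counts),
      env_load = sum(env_copies) * sc$env_scale,
      spike_copies = colSums(sc$mimic_copies),
      stringsAsFactors = FALSE
    )
    truth$expected_alr <- log10(truth$env_load / truth$spike_copies)
    spike_tab <- do.call(rbind, lapply(seq_len(sc$n_samples), function(j) {
      data.frame(sample = colnames(counts)[j], mimic = mimic_ids,
                 copies = sc$mimic_copies[, j], sample_amount = 1,
                 amount_unit = "reaction", amount_basis = "pcr",
                 stringsAsFactors = FALSE)
    }))
    list(table = count_table(counts), truth = truth,
         env_copies = env_copies, bias = bias,
         spike = spike_config(spike_tab))
  })
}

#' Assignment result by simulator naming convention
#'
#' The simulator names mimic features by their mimic id; this builds an
#' `assignment_result` from that convention, so simulated tables can flow
#' into [estimate_load()] without sequence alignment. Real data should use
#' [assign_features()].
#'
#' @param table a [count_table()].
#' @param mimic_ids feature ids that are mimics; everything else is
#'   environmental.
#' @return an `assignment_result`.
#' @export
assignment_from_names <- function(table, mimic_ids) {
  stopifnot(inherits(table, "count_table"))
  feats <- rownames(table$counts)
  missing <- setdiff(mimic_ids, feats)
  if (length(missing)) {
    stop("mimic ids not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  map <- setNames(ifelse(feats %in% mimic_ids, feats, "environmental"), feats)
  mimic_counts <- table$counts[mimic_ids, , drop = FALSE]
  env_rows <- setdiff(feats, mimic_ids)
  env_counts <- colSums(table$counts[env_rows, , drop = FALSE])
  structure(list(feature_map = map, mimic_counts = mimic_counts,
                 env_counts = env_counts,
                 total_counts = colSums(table$counts)),
            class = "assignment_result")
}

#' Simulate a spike-in dilution series
#'
#' A fixed environmental pool spiked with a dilution series of the mimic
#' panel: sample `i` receives `levels[i]` total mimic copies (split equally
#' across the panel). By design the ALR of environmental over mimic reads,
#' plotted against log10 spike copies, follows a line of slope -1.
#'
#' @param base a [sim_scenario()] providing the environmental pool, depth,
#'   bias and seed; its `mimic_copies` rownames define the panel.
#' @param levels total spike copies per sample (>= 2 values).
#' @return as [simulate_counts()], with `truth$expected_alr` the design
#'   expectation.
#' @export
simulate_dilution_series <- function(base, levels) {
  stopifnot(inherits(base, "sim_scenario"), length(levels) >= 2,
            all(levels > 0))
  panel <- rownames(base$mimic_copies)
  copies <- outer(rep(1 / length(panel), length(panel)), levels)
  rownames(copies) <- panel
  colnames(copies) <- sprintf("dil%02d", seq_along(levels))
  sc <- sim_scenario(
    n_env_taxa = base$n_env_taxa, env_meanlog = base$env_meanlog,
    env_sdlog = base$env_sdlog, mimic_copies = copies, depth = base$depth,
    env_scale = rep(1, length(levels)), bias_sdlog = base$bias_sdlog,
    seed = base$seed
  )
  simulate_counts(sc)
}

#' Simulate a single staggered-mix sample
#'
#' One sample spiked with a staggered mimic pool (each mimic at a different
#' known copy number), optionally on top of an environmental background.
#' The input for [staggered_curve()] testing.
#'
#' @param copies named vector of per-mimic spike copies.
#' @param depth reads for the sample.
#' @param seed integer seed.
#' @param env_total total environmental copies competing for reads
#'   (default 0: a pure spike-in pool).
#' @param bias_sdlog per-feature efficiency bias sd(log).
#' @return list with `table` (a [count_table()]) and `copies`.
#' @export
simulate_staggered_mix <- function(copies, depth = 1e5, seed = 1L,
                                   env_total = 0, bias_sdlog = 0) {
  stopifnot(!is.null(names(copies)), length(unique(copies)) >= 3,
            all(copies > 0))
  withr::with_seed(as.integer(seed), {
    ids <- names(copies)
    pool <- copies
    if (env_total > 0) pool <- c(pool, environmental = env_total)
    bias <- rlnorm(length(pool), 0, bias_sdlog)
    cnt <- rmultinom(1, size = depth, prob = pool * bias / sum(pool * bias))
    rownames(cnt) <- names(pool)
    colnames(cnt) <- "staggered"
    list(table = count_table(cnt), copies = copies)
  })
}

#' Simulate a bacterial/fungal ratio series with a cross-domain spike-in
#'
#' Emulates a series of samples holding total microbial load fixed while
#' sweeping the bacterial-to-fungal ratio. Each sample is sequenced in two
#' libraries (a fungal and a bacterial primer set); a single cross-domain
#' mimic construct, spiked at fixed copies, is amplified in both. Domain
#' compositions are fixed across samples and scaled by domain load, and
#' per-feature bias is constant across samples, so spike-in bias cancels in
#' differential and ratio estimates.
#'
#' @param bf_ratios true bacterial/fungal load ratios, one per sample.
#' @param total_load total (bacterial + fungal) rRNA operon copies per
#'   sample.
#' @param mimic_copies copies of the cross-domain mimic per sample.
#' @param n_taxa taxa per domain.
#' @param depth reads per library.
#' @param bias_sdlog per-feature efficiency bias sd(log) (default 0.5).
#' @param seed integer seed.
#' @return list with `fungal` and `bacterial` (each: `table`, `spike`,
#'   `assign`) and `truth` (data.frame: `sample`, `bact_load`, `fung_load`,
#'   `bf_ratio`).
#' @export
simulate_bf_series <- function(bf_ratios, total_load = 2e5,
                               mimic_copies = 1e4, n_taxa = 30L,
                               depth = 1e5, bias_sdlog = 0.5, seed = 1L) {
  stopifnot(length(bf_ratios) >= 2, all(bf_ratios > 0), total_load > 0,
            mimic_copies > 0)
  samples <- sprintf("mixBF%s", letters[seq_along(bf_ratios)])
  fung_load <- total_load / (1 + bf_ratios)
  bact_load <- total_load - fung_load
  withr::with_seed(as.integer(seed), {
    one_domain <- function(domain, loads) {
      taxa <- sprintf("%s%03d", substr(domain, 1, 1), seq_len(n_taxa))
      weights <- rlnorm(n_taxa, 0, 1)
      weights <- weights / sum(weights)
      bias <- setNames(rlnorm(n_taxa + 1L, 0, bias_sdlog),
                       c(taxa, "crossmimic"))
      counts <- matrix(0L, nrow = n_taxa + 1L, ncol = length(loads),
                       dimnames = list(c(taxa, "crossmimic"), samples))
      for (j in seq_along(loads)) {
        copies <- c(weights * loads[j], mimic_copies)
        probs <- copies * bias
        counts[, j] <- rmultinom(1, size = depth, prob = probs / sum(probs))
      }
      spike_tab <- data.frame(sample = samples, mimic = "crossmimic",
                              copies = mimic_copies, sample_amount = 1,
                              amount_unit = "reaction", amount_basis = "pcr",
                              stringsAsFactors = FALSE)
      tab <- count_table(counts)
      list(table = tab, spike = spike_config(spike_tab),
           assign = assignment_from_names(tab, "crossmimic"))
    }
    fungal <- one_domain("fungal", fung_load)
    bacterial <- one_domain("bacterial", bact_load)
    list(fungal = fungal, bacterial = bacterial,
         truth = data.frame(sample = samples, bact_load = bact_load,
                            fung_load = fung_load, bf_ratio = bf_ratios,
                            stringsAsFactors = FALSE))
  })
}
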