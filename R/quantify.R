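#' ASV count table
#'
#' A features x samples matrix of non-negative integer read counts, plus the
#' feature sequences. The container every quantification step consumes.
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param feature_seqs named character vector mapping feature id -> DNA
#'   string; may be `NULL` when sequences are not needed (e.g. after
#'   aggregation).
#' @return a `count_table`.
#' @export
count_table <- function(counts, feature_seqs = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(feature_seqs)) {
    missing <- setdiff(rownames(counts), names(feature_seqs))
    if (length(missing)) {
      stop("feature sequences missing for: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    feature_seqs <- feature_seqs[rownames(counts)]
  }
  structure(list(counts = counts, feature_seqs = feature_seqs),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", nrow(x$counts), "features x", ncol(x$counts),
      "samples;", sum(x$counts), "total reads\n")
  invisible(x)
}

#' Assign features to spike-in mimics
#'
#' Classifies every feature of a count table as one of the spike-in mimics
#' or as environmental. A feature is assigned to a mimic when its sequence
#' aligns to that mimic's reference (typically the predicted amplicon for
#' the sequenced primer set) at identity >= `min_identity`, using a glocal
#' alignment (feature global, reference local). Mimic panels are designed to
#' be mutually dissimilar, so a feature matching two mimics indicates a
#' broken panel and is an error. Counts of multiple features assigned to the
#' same mimic are summed; everything unassigned is summed as environmental.
#'
#' @param table a [count_table()] with feature sequences.
#' @param panel named character vector of mimic reference sequences
#'   (amplicons or full constructs).
#' @param min_identity assignment threshold (default 0.97).
#' @return an `assignment_result`: list with `feature_map` (feature ->
#'   mimic id or `"environmental"`), `mimic_counts` (mimics x samples
#'   matrix), `env_counts` (named vector per sample) and `total_counts`.
#' @export
assign_features <- function(table, panel, min_identity = 0.97) {
  stopifnot(inherits(table, "count_table"), length(panel) >= 1,
            !is.null(names(panel)))
  if (is.null(table$feature_seqs)) {
    stop("count table has no feature sequences", call. = FALSE)
  }
  feats <- rownames(table$counts)
  map <- setNames(rep("environmental", length(feats)), feats)
  panel_set <- Biostrings::DNAStringSet(unlist(panel))
  for (f in feats) {
    fs <- Biostrings::DNAString(table$feature_seqs[[f]])
    ids <- vapply(seq_along(panel_set), function(i) {
      aln <- Biostrings::pairwiseAlignment(fs, panel_set[[i]],
                                           type = "global-local")
      Biostrings::nmatch(aln) / length(fs)
    }, numeric(1))
    hits <- names(panel)[ids >= min_identity]
    if (length(hits) > 1L) {
      stop("feature ", f, " matches multiple mimics (",
           paste(hits, collapse = ", "), ") at identity >= ", min_identity,
           call. = FALSE)
    }
    if (length(hits) == 1L) map[f] <- hits
  }
  mimic_counts <- matrix(0L, nrow = length(panel), ncol = ncol(table$counts),
                         dimnames = list(names(panel), colnames(table$counts)))
  for (m in names(panel)) {
    rows <- names(map)[map == m]
    if (length(rows)) {
      mimic_counts[m, ] <- as.integer(colSums(table$counts[rows, , drop = FALSE]))
    }
  }
  env_rows <- names(map)[map == "environmental"]
  env_counts <- if (length(env_rows)) {
    colSums(table$counts[env_rows, , drop = FALSE])
  } else {
    setNames(rep(0, ncol(table$counts)), colnames(table$counts))
  }
  structure(list(feature_map = map,
                 mimic_counts = mimic_counts,
                 env_counts = env_counts,
                 total_counts = colSums(table$counts)),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  n_mimic <- sum(x$feature_map != "environmental")
  cat("Assignment:", n_mimic, "mimic feature(s),",
      sum(x$feature_map == "environmental"), "environmental feature(s)\n")
  cat("Mimic read fraction per sample:\n")
  print(round(colSums(x$mimic_counts) / x$total_counts, 4))
  invisible(x)
}

#' Rarefy a count table
#'
#' Random subsampling without replacement of every sample column to a fixed
#' depth (multivariate hypergeometric per column), via [vegan::rrarefy()].
#'
#' @param table a [count_table()].
#' @param depth target reads per sample; must not exceed any column sum.
#' @param seed integer seed for reproducibility.
#' @return a rarefied [count_table()] (feature sequences carried over).
#' @export
rarefy_counts <- function(table, depth, seed) {
  stopifnot(inherits(table, "count_table"), depth >= 1)
  cs <- colSums(table$counts)
  low <- cs < depth
  if (any(low)) {
    stop("depth ", depth, " exceeds reads in sample(s): ",
         paste(names(cs)[low], collapse = ", "), call. = FALSE)
  }
  sub <- withr::with_seed(as.integer(seed), {
    withCallingHandlers(
      t(vegan::rrarefy(t(table$counts), sample = depth)),
      # vegan's "observed counts" heuristic misfires on spike-in tables
      # without singletons; subsampling itself is unaffected
      warning = function(w) {
        if (grepl("smallest count", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  dimnames(sub) <- dimnames(table$counts)
  count_table(sub, table$feature_seqs)
}

#' Additive log-ratio of environmental to spike-in reads
#'
#' `log10(env_count / mimic_count)`: the scaling factor that anchors
#' compositional read counts to the known number of spike-in copies.
#'
#' @param env_count environmental (non-mimic) read count.
#' @param mimic_count spike-in (mimic) read count in the same sample.
#' @param pseudocount optional value (e.g. 0.5) added to both counts; by
#'   default zero mimic reads are an error, mirroring sample exclusion
#'   rather than imputation.
#' @return log10 ratio (vectorized over paired inputs).
#' @export
#' @examples
#' alr_transform(1000, 10)  # 2
alr_transform <- function(env_count, mimic_count, pseudocount = NULL) {
  stopifnot(length(env_count) == length(mimic_count),
            all(env_count >= 0), all(mimic_count >= 0))
  if (is.null(pseudocount)) {
    if (any(mimic_count == 0)) {
      stop("insufficient spike-in reads: mimic count is zero ",
           "(set a pseudocount to override)", call. = FALSE)
    }
    if (any(env_count == 0)) {
      stop("environmental count is zero (set a pseudocount to override)",
           call. = FALSE)
    }
    log10(env_count / mimic_count)
  } else {
    stopifnot(pseudocount > 0)
    log10((env_count + pseudocount) / (mimic_count + pseudocount))
  }
}

#' Spike-in configuration
#'
#' Per-sample record of how many copies of each mimic were added and how
#' much sample material the extraction covered.
#'
#' @param samples data.frame with columns `sample`, `mimic`, `copies` and
#'   per-sample `sample_amount`, `amount_unit`, `amount_basis`
#'   (`"extraction"` or `"pcr"`).
#' @return a `spike_config`.
#' @export
spike_config <- function(samples) {
  need <- c("sample", "mimic", "copies", "sample_amount", "amount_unit",
            "amount_basis")
  stopifnot(is.data.frame(samples), all(need %in% names(samples)))
  if (any(samples$copies <= 0)) stop("copies must be > 0", call. = FALSE)
  if (any(samples$sample_amount <= 0)) {
    stop("sample_amount must be > 0", call. = FALSE)
  }
  stopifnot(all(samples$amount_basis %in% c("extraction", "pcr")))
  structure(list(table = samples), class = "spike_config")
}

spike_copies <- function(spike, sample, mimic = NULL) {
  tab <- spike$table[spike$table$sample == sample, , drop = FALSE]
  if (is.null(mimic)) return(sum(tab$copies))
  tab$copies[match(mimic, tab$mimic)]
}

#' Estimate absolute microbial loads
#'
#' Converts environmental read counts to absolute copy numbers using the
#' spike-in as reference:
#' `absolute_load = env_reads / mimic_reads * copies_added`, equivalently
#' `10^ALR * copies_added`. With `reference = "aggregate"` the summed mimic
#' reads and summed copies of all mimics detected in the sample are used.
#' Samples whose reference mimic has fewer than `min_mimic_reads` reads are
#' flagged `low_spike_reads` and get `NA` estimates rather than unstable
#' numbers.
#'
#' @param assign an [assign_features()] result.
#' @param spike a [spike_config()].
#' @param reference a mimic id, or `"aggregate"`.
#' @param min_mimic_reads QC threshold on reference reads (default 50).
#' @return data.frame (one row per sample): `sample`, `reference`,
#'   `mimic_reads`, `env_reads`, `copies_added`, `alr`, `absolute_load`,
#'   `normalized_load`, `amount_unit`, `amount_basis`, `flag`.
#' @export
estimate_load <- function(assign, spike, reference = "aggregate",
                          min_mimic_reads = 50L) {
  stopifnot(inherits(assign, "assignment_result"),
            inherits(spike, "spike_config"))
  samples <- colnames(assign$mimic_counts)
  rows <- lapply(samples, function(s) {
    stab <- spike$table[spike$table$sample == s, , drop = FALSE]
    if (!nrow(stab)) {
      stop("no spike-in metadata for sample ", s, call. = FALSE)
    }
    if (length(unique(stab$amount_basis)) != 1L) {
      stop("conflicting amount_basis for sample ", s, call. = FALSE)
    }
    if (identical(reference, "aggregate")) {
      detected <- rownames(assign$mimic_counts)[assign$mimic_counts[, s] > 0]
      declared <- intersect(detected, stab$mimic)
      mimic_reads <- sum(assign$mimic_counts[declared, s])
      copies <- sum(stab$copies[stab$mimic %in% declared])
    } else {
      if (!reference %in% rownames(assign$mimic_counts)) {
        stop("reference mimic ", reference, " not in assignment", call. = FALSE)
      }
      if (!reference %in% stab$mimic) {
        stop("reference mimic ", reference, " not spiked into sample ", s,
             call. = FALSE)
      }
      mimic_reads <- assign$mimic_counts[reference, s]
      copies <- stab$copies[match(reference, stab$mimic)]
    }
    env <- assign$env_counts[[s]]
    ok <- mimic_reads >= min_mimic_reads
    alr <- if (ok) log10(env / mimic_reads) else NA_real_
    abs_load <- if (ok) env / mimic_reads * copies else NA_real_
    data.frame(
      sample = s, reference = reference,
      mimic_reads = mimic_reads, env_reads = env, copies_added = copies,
      alr = alr, absolute_load = abs_load,
      normalized_load = abs_load / stab$sample_amount[1],
      amount_unit = stab$amount_unit[1], amount_basis = stab$amount_basis[1],
      flag = if (ok) "" else "low_spike_reads",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Differential loads between sample pairs
#'
#' Log10 fold differences in absolute load between all ordered sample pairs:
#' `delta = alr_1 - alr_2 + log10(copies_1 / copies_2)`, which reduces to
#' the ALR difference when both samples received the same spike level.
#' Antisymmetric in the pair order. Flagged samples are dropped.
#'
#' @param loads an [estimate_load()] result (single shared reference).
#' @return data.frame with `sample_1`, `sample_2`, `delta_log10`.
#' @export
differential_load <- function(loads) {
  stopifnot(is.data.frame(loads), length(unique(loads$reference)) == 1L)
  keep <- loads[loads$flag == "", , drop = FALSE]
  n <- nrow(keep)
  if (n < 2L) {
    return(data.frame(sample_1 = character(0), sample_2 = character(0),
                      delta_log10 = numeric(0)))
  }
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  data.frame(
    sample_1 = keep$sample[pairs$i],
    sample_2 = keep$sample[pairs$j],
    delta_log10 = (keep$alr[pairs$i] - keep$alr[pairs$j]) +
      log10(keep$copies_added[pairs$i] / keep$copies_added[pairs$j]),
    stringsAsFactors = FALSE
  )
}

#' Geometric mean of absolute fold differences
#'
#' `exp(mean(|ln(measured/expected)|))`: the standard agreement statistic for
#' spike-in experiments. Always >= 1, and exactly 1 only for perfect
#' agreement; equivalent to the mean of absolute differences of
#' log-transformed values, in any log base.
#'
#' @param measured,expected paired positive values.
#' @return scalar gmAFD.
#' @export
#' @examples
#' gmafd(c(2, 0.5), c(1, 1))  # 2
gmafd <- function(measured, expected) {
  stopifnot(length(measured) == length(expected), length(measured) >= 1)
  if (any(!is.finite(measured)) || any(!is.finite(expected)) ||
      any(measured <= 0) || any(expected <= 0)) {
    stop("gmafd requires finite positive paired values", call. = FALSE)
  }
  exp(mean(abs(log(measured / expected))))
}

#' Bacterial-to-fungal load ratio
#'
#' Ratio of absolute bacterial to fungal load in one sample. When both loads
#' are derived from the same cross-domain construct the spike copies cancel
#' and the ratio is calibration-free.
#'
#' @param bact_load,fung_load single rows of [estimate_load()] results for
#'   the same sample (bacterial and fungal libraries respectively).
#' @return scalar ratio.
#' @export
bf_ratio <- function(bact_load, fung_load) {
  stopifnot(is.data.frame(bact_load), is.data.frame(fung_load),
            nrow(bact_load) == 1L, nrow(fung_load) == 1L)
  if (bact_load$sample != fung_load$sample) {
    stop("BF ratio requires loads from the same sample", call. = FALSE)
  }
  if (!is.finite(fung_load$absolute_load) || fung_load$absolute_load <= 0) {
    stop("fungal load is zero or unavailable", call. = FALSE)
  }
  if (!is.finite(bact_load$absolute_load)) {
    stop("bacterial load is unavailable", call. = FALSE)
  }
  bact_load$absolute_load / fung_load$absolute_load
}
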