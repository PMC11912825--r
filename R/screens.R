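#' Longest homopolymer run
#'
#' Length of the longest mononucleotide run in a sequence. Spike-in variable
#' regions are designed to avoid runs longer than 3 bp, which are error-prone
#' during synthesis and Illumina sequencing.
#'
#' @param seq DNA string (A/C/G/T).
#' @return integer, the longest run length.
#' @export
#' @examples
#' scan_homopolymers("AAAAT")  # 4
scan_homopolymers <- function(seq) {
  seq <- assert_dna(seq)
  max(rle(seq_chars(seq))$lengths)
}

# does any substring of length k occur at >= 2 distinct start positions?
has_direct_repeat <- function(seq, k) {
  km <- kmers_of(seq, k)
  anyDuplicated(km) > 0L
}

# does any substring of length k have its reverse complement also present?
# (the k-mers of revcomp(seq) are exactly the reverse complements of the
# k-mers of seq, so one whole-sequence revcomp suffices)
has_inverted_repeat <- function(seq, k, rc = revcomp(seq)) {
  km <- kmers_of(seq, k)
  length(km) && any(km %in% kmers_of(rc, k))
}

# binary search for the largest k in [lo, hi] with pred(k) TRUE; pred is
# monotone (TRUE for all k below some threshold). Returns 0 if none.
largest_true <- function(pred, lo, hi) {
  if (hi < lo || !pred(lo)) return(0L)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (pred(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Longest direct and inverted repeats
#'
#' Finds the longest substring occurring at two or more positions (direct
#' repeat) and the longest substring whose reverse complement also occurs in
#' the sequence (inverted repeat; overlapping occurrences and self-palindromes
#' count). The inverted-repeat screen doubles as a hairpin-formation proxy.
#'
#' @param seq DNA string.
#' @param min_len smallest repeat length of interest (>= 2); lengths below
#'   `min_len` are reported as 0.
#' @return named integer vector `c(max_direct =, max_inverted =)`.
#' @export
#' @examples
#' scan_repeats("ACGTACGT", min_len = 2)   # direct repeat of 4
#' scan_repeats("AAGCTT", min_len = 2)     # palindrome: inverted repeat of 6
scan_repeats <- function(seq, min_len = 2L) {
  seq <- assert_dna(seq)
  stopifnot(min_len >= 2L)
  n <- nchar(seq)
  rc <- revcomp(seq)
  dir <- largest_true(function(k) has_direct_repeat(seq, k), min_len, n - 1L)
  inv <- largest_true(function(k) has_inverted_repeat(seq, k, rc), min_len, n)
  c(max_direct = dir, max_inverted = inv)
}

#' Sliding-window GC deviation
#'
#' Maximum absolute deviation of window GC content from a reference GC
#' content, in percentage points, over all windows of size `window` at
#' `step`-bp offsets (the final window is anchored at the sequence end so the
#' 3' tail is always covered).
#'
#' @param seq DNA string.
#' @param window window size in bp (must not exceed the sequence length).
#' @param step offset between window starts in bp.
#' @param reference_gc GC fraction to compare against; defaults to the overall
#'   GC content of `seq`.
#' @return numeric, maximum deviation in percentage points.
#' @export
scan_gc_windows <- function(seq, window, step = 10L,
                            reference_gc = gc_fraction(seq)) {
  seq <- assert_dna(seq)
  n <- nchar(seq)
  if (window > n) stop("window (", window, ") exceeds sequence length (", n, ")",
                       call. = FALSE)
  stopifnot(step >= 1L, reference_gc >= 0, reference_gc <= 1)
  is_gc <- seq_chars(seq) %in% c("G", "C")
  cum <- c(0L, cumsum(is_gc))
  starts <- unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
  win_gc <- (cum[starts + window] - cum[starts]) / window
  100 * max(abs(win_gc - reference_gc))
}

# expand one IUPAC string into all concrete A/C/G/T strings; errors on
# invalid characters, capped to avoid pathological degeneracy
expand_iupac <- function(seq, max_expansion = 10000L) {
  seq <- assert_dna(seq, what = "IUPAC string", allow_iupac = TRUE)
  sets <- IUPAC_MAP[seq_chars(seq)]
  n_total <- prod(lengths(sets))
  if (n_total > max_expansion) {
    stop("IUPAC expansion of ", seq, " yields ", n_total,
         " variants (cap ", max_expansion, ")", call. = FALSE)
  }
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

# the set of all concrete k-mers found in any primer or its reverse
# complement, after IUPAC expansion; used as the prohibited-k-mer dictionary
prohibited_kmer_set <- function(primers, k) {
  out <- character(0)
  for (p in primers) {
    p <- assert_dna(p, what = "primer", allow_iupac = TRUE)
    if (k > nchar(p)) {
      stop("k (", k, ") exceeds primer length (", nchar(p), ")", call. = FALSE)
    }
    for (orient in c(p, revcomp(p))) {
      for (w in kmers_of(orient, k)) {
        out <- c(out, expand_iupac(w))
      }
    }
  }
  unique(out)
}

#' Count prohibited primer-derived k-mers
#'
#' Counts forward-strand positions in `seq` whose k-mer matches any k-mer of
#' any primer (IUPAC-expanded) or its reverse complement. Designed variable
#' regions must contain zero such positions so that spike-in amplicons cannot
#' acquire spurious internal primer-binding sites.
#'
#' @param seq DNA string to screen.
#' @param primers character vector of primer sequences (IUPAC alphabet).
#' @param k k-mer length (default 8); must not exceed the shortest primer.
#' @param kmer_set optional precomputed dictionary from
#'   [prohibited_kmer_set()]-like expansion (internal fast path).
#' @return integer count of matching positions.
#' @export
scan_prohibited_kmers <- function(seq, primers, k = 8L, kmer_set = NULL) {
  seq <- assert_dna(seq)
  if (is.null(kmer_set)) kmer_set <- prohibited_kmer_set(primers, k)
  sum(kmers_of(seq, k) %in% kmer_set)
}

# |freq(A) - freq(T)| and |freq(G) - freq(C)|, returned as the larger of the
# two; the designer's "balanced base composition" metric
composition_imbalance <- function(seq) {
  chars <- seq_chars(assert_dna(seq))
  f <- table(factor(chars, levels = DNA_BASES)) / length(chars)
  max(abs(f[["A"]] - f[["T"]]), abs(f[["G"]] - f[["C"]]))
}

# fast pass/fail version of screen_sequence for the assembly hot loop:
# short-circuits on the first violated constraint and tests repeats by
# existence at max_repeat + 1 rather than computing exact maxima. Returns
# "" on pass, else the name of the violated metric. Semantics identical to
# screen_sequence()$passed.
screen_violation <- function(seq, cfg, kmer_set = character(0)) {
  chars <- seq_chars(seq)
  n <- length(chars)
  if (max(rle(chars)$lengths) > cfg$max_homopolymer) {
    return("max_homopolymer_run")
  }
  f <- tabulate(match(chars, DNA_BASES), nbins = 4L) / n
  if (max(abs(f[1] - f[4]), abs(f[3] - f[2])) >
      cfg$composition_balance_tolerance) {
    return("composition_imbalance")
  }
  is_gc <- chars == "G" | chars == "C"
  if (n >= cfg$gc_window_size) {
    cum <- c(0L, cumsum(is_gc))
    w <- cfg$gc_window_size
    starts <- unique(c(seq(1L, n - w + 1L, by = cfg$gc_window_step),
                       n - w + 1L))
    win_gc <- (cum[starts + w] - cum[starts]) / w
    dev <- 100 * max(abs(win_gc - mean(is_gc)))
  } else {
    dev <- 100 * abs(mean(is_gc) - cfg$target_gc)
  }
  if (dev > cfg$gc_window_tolerance) return("max_gc_window_deviation")
  if (length(kmer_set) &&
      any(kmers_of(seq, cfg$prohibited_kmer_length) %in% kmer_set)) {
    return("prohibited_kmer_hits")
  }
  if (has_direct_repeat(seq, cfg$max_repeat + 1L)) {
    return("max_direct_repeat")
  }
  if (has_inverted_repeat(seq, cfg$max_repeat + 1L)) {
    return("max_inverted_repeat")
  }
  ""
}

#' Run all designer screens on a sequence
#'
#' Computes every screening metric of the designer (homopolymer run, direct
#' and inverted repeats, windowed GC deviation, prohibited primer k-mers and
#' base-composition balance) and compares each against its configured
#' threshold.
#'
#' @param seq DNA string.
#' @param cfg a [design_config()] object.
#' @param kmer_set optional precomputed prohibited-k-mer dictionary.
#' @return a `screen_report` list: one entry per metric plus `passed`.
#' @export
screen_sequence <- function(seq, cfg, kmer_set = NULL) {
  seq <- assert_dna(seq)
  n <- nchar(seq)
  rep_scan <- scan_repeats(seq, min_len = 2L)
  gc_dev <- if (n >= cfg$gc_window_size) {
    scan_gc_windows(seq, cfg$gc_window_size, cfg$gc_window_step)
  } else {
    # below one window, check the whole-sequence GC against the target
    100 * abs(gc_fraction(seq) - cfg$target_gc)
  }
  if (is.null(kmer_set) && length(cfg$prohibited_sources)) {
    kmer_set <- prohibited_kmer_set(cfg$prohibited_sources,
                                    cfg$prohibited_kmer_length)
  }
  hits <- if (length(kmer_set)) {
    scan_prohibited_kmers(seq, kmer_set = kmer_set,
                          k = cfg$prohibited_kmer_length)
  } else 0L
  report <- list(
    max_homopolymer_run = scan_homopolymers(seq),
    max_direct_repeat = unname(rep_scan["max_direct"]),
    max_inverted_repeat = unname(rep_scan["max_inverted"]),
    max_gc_window_deviation = gc_dev,
    prohibited_kmer_hits = hits,
    composition_imbalance = composition_imbalance(seq)
  )
  report$passed <-
    report$max_homopolymer_run <= cfg$max_homopolymer &&
    report$max_direct_repeat <= cfg$max_repeat &&
    report$max_inverted_repeat <= cfg$max_repeat &&
    report$max_gc_window_deviation <= cfg$gc_window_tolerance &&
    report$prohibited_kmer_hits == 0L &&
    report$composition_imbalance <= cfg$composition_balance_tolerance
  structure(report, class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen report (", if (x$passed) "PASSED" else "FAILED", ")\n", sep = "")
  for (m in setdiff(names(x), "passed")) {
    cat(sprintf("  %-26s %s\n", m, format(x[[m]], digits = 4)))
  }
  invisible(x)
}
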