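#' Designer configuration
#'
#' Bundles every tunable of the artificial-sequence designer. Defaults encode
#' the standard screening rules for synthetic spike-in variable regions:
#' homopolymers capped at 3 bp, direct/inverted repeats at 8 bp, sliding
#' window GC within 2.5 percentage points of the overall GC, no 8-mer shared
#' with any PCR primer, pairwise local alignments at most 16 bp, and
#' A/T and G/C frequencies balanced to within 0.05.
#'
#' @param target_gc desired GC content as a fraction in (0, 1); panels are
#'   conventionally designed at 0.40, 0.50 and 0.60.
#' @param target_length final sequence length in bp (>= `seed_kmer_length`).
#' @param seed_kmer_length length of the random building-block k-mers
#'   (default 20 bp).
#' @param max_homopolymer longest allowed mononucleotide run (bp).
#' @param max_repeat longest allowed direct or inverted repeat (bp).
#' @param gc_window_tolerance allowed deviation of window GC from overall GC,
#'   in percentage points.
#' @param gc_window_size,gc_window_step sliding-window geometry (bp); windows
#'   are skipped while the sequence is shorter than one window, in which case
#'   whole-sequence GC is checked against `target_gc` instead.
#' @param max_cross_alignment longest allowed pairwise local alignment (and
#'   longest shared exact substring) within a designed panel, in bp.
#' @param prohibited_kmer_length k for the prohibited primer k-mer screen.
#' @param prohibited_sources character vector of primer sequences (IUPAC
#'   alphabet) whose k-mers (both strands) must not occur in designed
#'   sequences. Defaults to the primers of [default_primer_sets()].
#' @param composition_balance_tolerance maximum allowed |freq(A)-freq(T)| and
#'   |freq(G)-freq(C)|.
#' @param rng_seed integer seed making the design reproducible; `NULL` uses
#'   the current RNG state.
#' @param max_attempts global cap on candidate k-mer draws before the design
#'   aborts with an error.
#' @return a `design_config` list.
#' @export
#' @examples
#' cfg <- design_config(target_gc = 0.5, target_length = 400, rng_seed = 1)
design_config <- function(target_gc = 0.5,
                          target_length = 400L,
                          seed_kmer_length = 20L,
                          max_homopolymer = 3L,
                          max_repeat = 8L,
                          gc_window_tolerance = 2.5,
                          gc_window_size = 100L,
                          gc_window_step = 10L,
                          max_cross_alignment = 16L,
                          prohibited_kmer_length = 8L,
                          prohibited_sources = default_primer_sets()$all_primers,
                          composition_balance_tolerance = 0.05,
                          rng_seed = NULL,
                          max_attempts = 200000L) {
  cfg <- list(
    target_gc = target_gc, target_length = as.integer(target_length),
    seed_kmer_length = as.integer(seed_kmer_length),
    max_homopolymer = as.integer(max_homopolymer),
    max_repeat = as.integer(max_repeat),
    gc_window_tolerance = gc_window_tolerance,
    gc_window_size = as.integer(gc_window_size),
    gc_window_step = as.integer(gc_window_step),
    max_cross_alignment = as.integer(max_cross_alignment),
    prohibited_kmer_length = as.integer(prohibited_kmer_length),
    prohibited_sources = prohibited_sources,
    composition_balance_tolerance = composition_balance_tolerance,
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
    max_attempts = as.integer(max_attempts)
  )
  validate_design_config(cfg)
  structure(cfg, class = "design_config")
}

validate_design_config <- function(cfg) {
  stopifnot(
    cfg$target_gc > 0, cfg$target_gc < 1,
    cfg$target_length >= cfg$seed_kmer_length,
    cfg$seed_kmer_length >= 2L,
    cfg$max_homopolymer >= 1L, cfg$max_repeat >= 2L,
    cfg$gc_window_tolerance > 0, cfg$gc_window_size >= 10L,
    cfg$gc_window_step >= 1L, cfg$max_cross_alignment >= 1L,
    cfg$prohibited_kmer_length >= 4L,
    cfg$composition_balance_tolerance > 0,
    cfg$max_attempts >= 1L
  )
  for (p in cfg$prohibited_sources) {
    assert_dna(p, what = "prohibited source primer", allow_iupac = TRUE)
  }
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("Design config: length", x$target_length, "bp, GC target",
      sprintf("%.0f%%", 100 * x$target_gc), "\n")
  cat("  screens: homopolymer <=", x$max_homopolymer,
      "| repeats <=", x$max_repeat,
      "| GC window +/-", x$gc_window_tolerance, "pp",
      "| cross-alignment <=", x$max_cross_alignment, "\n")
  cat("  prohibited:", length(x$prohibited_sources), "primer(s), k =",
      x$prohibited_kmer_length, "\n")
  invisible(x)
}

#' Commonly used rRNA-operon primer sets
#'
#' Field-standard primer pairs for the loci a cross-domain spike-in panel is
#' built around: the eukaryotic SSU V9 region, the fungal internal
#' transcribed spacers ITS1 and ITS2, the fungal LSU D1/D2 domain, and the
#' bacterial 16S SSU V4 region (Earth Microbiome Project primers). These are
#' widely used community-profiling primers; any primer table in the same
#' shape can be substituted.
#'
#' @return list with `primers` (data.frame: name, forward, reverse) and
#'   `all_primers` (character vector of every primer sequence).
#' @export
default_primer_sets <- function() {
  primers <- data.frame(
    name = c("SSU-V9", "ITS1", "ITS2", "LSU-D1D2", "SSU-V4"),
    forward = c(
      "GTACACACCGCCCGTC",        # 1391f
      "CTTGGTCATTTAGAGGAAGTAA",  # ITS1-F
      "GCATCGATGAAGAACGCAGC",    # ITS3
      "GCATATCAATAAGCGGAGGAAAAG", # NL1
      "GTGYCAGCMGCCGCGGTAA"      # 515F
    ),
    reverse = c(
      "TGATCCTTCTGCAGGTTCACCTAC", # EukBr
      "GCTGCGTTCTTCATCGATGC",     # ITS2 (= revcomp target of ITS3 region)
      "TCCTCCGCTTATTGATATGC",     # ITS4
      "GGTCCGTGTTTCAAGACGG",      # LR3r
      "GGACTACNVGGGTWTCTAAT"      # 806R
    ),
    stringsAsFactors = FALSE
  )
  list(primers = primers,
       all_primers = unique(c(primers$forward, primers$reverse)))
}

#' Default panel configurations
#'
#' A standard spike-in variable-region panel: three GC targets (40, 50 and
#' 60%) crossed with three lengths spanning the sizes of rRNA-operon variable
#' regions, giving nine configurations. Seeds are derived deterministically
#' from `rng_seed` so the whole panel is reproducible.
#'
#' @param gc_targets GC fractions to cover.
#' @param lengths sequence lengths (bp) to cover.
#' @param rng_seed master seed for the panel.
#' @param ... passed on to [design_config()].
#' @return list of `design_config` objects.
#' @export
default_design_configs <- function(gc_targets = c(0.4, 0.5, 0.6),
                                   lengths = c(300L, 450L, 600L),
                                   rng_seed = 1L, ...) {
  grid <- expand.grid(gc = gc_targets, len = lengths)
  lapply(seq_len(nrow(grid)), function(i) {
    design_config(target_gc = grid$gc[i], target_length = grid$len[i],
                  rng_seed = derive_seed(rng_seed, paste0("panel", i)), ...)
  })
}
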