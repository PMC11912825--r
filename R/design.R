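#' Generate random seed k-mers
#'
#' Draws `n` random k-mers with exactly `round(target_gc * k)` G/C bases and
#' no homopolymer run longer than `cfg$max_homopolymer`. These are the
#' building blocks that [assemble_sequence()] concatenates into full
#' artificial variable regions.
#'
#' @param cfg a [design_config()].
#' @param n number of k-mers to generate.
#' @return character vector of `n` k-mers of length `cfg$seed_kmer_length`.
#' @export
#' @examples
#' generate_seed_kmers(design_config(rng_seed = 42), n = 5)
generate_seed_kmers <- function(cfg, n) {
  validate_design_config(cfg)
  stopifnot(n >= 1)
  draw <- function() {
    out <- character(n)
    got <- 0L
    attempts <- 0L
    while (got < n) {
      attempts <- attempts + 1L
      if (attempts > cfg$max_attempts) {
        stop("constraints unsatisfiable: could not generate seed k-mers ",
             "with GC ", cfg$target_gc, " and homopolymer <= ",
             cfg$max_homopolymer, " within max_attempts", call. = FALSE)
      }
      cand <- random_kmer(cfg$seed_kmer_length, cfg$target_gc)
      if (max(rle(seq_chars(cand))$lengths) <= cfg$max_homopolymer) {
        got <- got + 1L
        out[got] <- cand
      }
    }
    out
  }
  if (!is.null(cfg$rng_seed)) withr::with_seed(cfg$rng_seed, draw()) else draw()
}

# one random k-mer with exactly round(gc * k) G/C bases
random_kmer <- function(k, gc) {
  n_gc <- round(gc * k)
  if (n_gc < 0L || n_gc > k) {
    stop("constraints unsatisfiable: target_gc ", gc,
         " incompatible with k-mer length ", k, call. = FALSE)
  }
  chars <- character(k)
  gc_pos <- sample.int(k, n_gc)
  chars[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  chars[-gc_pos] <- sample(c("A", "T"), k - n_gc, replace = TRUE)
  if (n_gc == k) chars <- sample(c("G", "C"), k, replace = TRUE)
  if (n_gc == 0L) chars <- sample(c("A", "T"), k, replace = TRUE)
  paste(chars, collapse = "")
}

#' Assemble an artificial sequence by progressive k-mer extension
#'
#' Grows a sequence to `cfg$target_length` by repeatedly appending random
#' seed k-mers, re-running every screen on the extended sequence at each
#' step. Candidates failing any screen are rejected and resampled; when no
#' candidate passes after `resamples_per_step` draws the assembly backtracks
#' by removing the previous extension (up to `max_backtrack` consecutive
#' steps). The final extension is truncated so the returned sequence has
#' exactly the target length.
#'
#' @param cfg a [design_config()].
#' @param id identifier recorded on the result.
#' @param resamples_per_step candidate draws per extension step before
#'   backtracking (default 200).
#' @param max_backtrack maximum consecutive backtracking steps (default 5).
#' @return an `artificial_sequence`: list with `id`, `sequence`, `gc`,
#'   `screen` (a `screen_report`, always passing) and `config`.
#' @export
#' @examples
#' art <- assemble_sequence(design_config(target_length = 100, rng_seed = 7))
#' art$screen$passed
assemble_sequence <- function(cfg, id = "art1", resamples_per_step = 200L,
                              max_backtrack = 5L) {
  validate_design_config(cfg)
  run <- function() {
    kmer_set <- if (length(cfg$prohibited_sources)) {
      prohibited_kmer_set(cfg$prohibited_sources, cfg$prohibited_kmer_length)
    } else character(0)
    k <- cfg$seed_kmer_length
    seq <- ""
    draws <- 0L
    backtracks <- 0L
    fail_tally <- integer(0)
    repeat {
      if (nchar(seq) >= cfg$target_length) break
      step_ok <- FALSE
      for (. in seq_len(resamples_per_step)) {
        draws <- draws + 1L
        if (draws > cfg$max_attempts) {
          worst <- if (length(fail_tally)) {
            names(which.max(fail_tally))
          } else "none"
          stop("design failed: max_attempts (", cfg$max_attempts,
               ") exhausted at length ", nchar(seq),
               "; most-violated constraint: ", worst, call. = FALSE)
        }
        cand <- random_kmer(k, cfg$target_gc)
        if (max(rle(seq_chars(cand))$lengths) > cfg$max_homopolymer) next
        ext <- paste0(seq, cand)
        if (nchar(ext) > cfg$target_length) {
          ext <- substr(ext, 1L, cfg$target_length)
        }
        violated <- screen_violation(ext, cfg, kmer_set = kmer_set)
        if (!nzchar(violated)) {
          seq <- ext
          step_ok <- TRUE
          backtracks <- 0L
          break
        } else {
          fail_tally[violated] <- if (is.na(fail_tally[violated])) {
            1L
          } else fail_tally[violated] + 1L
        }
      }
      if (!step_ok) {
        if (backtracks >= max_backtrack || nchar(seq) <= k) {
          seq <- ""
          backtracks <- 0L
        } else {
          seq <- substr(seq, 1L, nchar(seq) - k)
          backtracks <- backtracks + 1L
        }
      }
    }
    screen <- screen_sequence(seq, cfg, kmer_set = kmer_set)
    stopifnot(screen$passed)
    structure(list(id = id, sequence = seq, gc = gc_fraction(seq),
                   screen = screen, config = cfg),
              class = "artificial_sequence")
  }
  if (!is.null(cfg$rng_seed)) withr::with_seed(cfg$rng_seed, run()) else run()
}

#' @export
print.artificial_sequence <- function(x, ...) {
  cat("Artificial sequence", x$id, "-", nchar(x$sequence), "bp, GC",
      sprintf("%.1f%%", 100 * x$gc), "\n")
  print(x$screen)
  invisible(x)
}

#' Design a mutually dissimilar panel of artificial sequences
#'
#' Assembles one artificial sequence per configuration and enforces the
#' between-sequence screen: every pair must have a local alignment of at most
#' `max_cross_alignment` aligned columns ([cross_similarity()]) and share no
#' exact substring longer than that ([longest_shared_substring()]). Sequences
#' failing the pairwise screen are regenerated from a deterministically
#' bumped seed, so identical configurations always yield an identical panel.
#'
#' @param cfg_list list of [design_config()] objects (one sequence each).
#' @param ids identifiers; default `art01`, `art02`, ...
#' @param max_regen regeneration attempts per panel member before erroring.
#' @return list of `artificial_sequence` objects.
#' @export
design_panel <- function(cfg_list, ids = NULL, max_regen = 25L) {
  stopifnot(length(cfg_list) >= 1)
  if (inherits(cfg_list, "design_config")) cfg_list <- list(cfg_list)
  if (is.null(ids)) {
    ids <- sprintf("art%02d", seq_along(cfg_list))
  }
  stopifnot(length(ids) == length(cfg_list))
  panel <- vector("list", length(cfg_list))
  for (i in seq_along(cfg_list)) {
    cfg <- cfg_list[[i]]
    validate_design_config(cfg)
    accepted <- FALSE
    for (retry in 0:max_regen) {
      cfg_i <- cfg
      if (retry > 0) {
        base <- if (is.null(cfg$rng_seed)) 0L else cfg$rng_seed
        cfg_i$rng_seed <- as.integer((base + 7919 * retry) %% 2147483647)
      }
      cand <- assemble_sequence(cfg_i, id = ids[i])
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        lim <- max(cfg_i$max_cross_alignment,
                   panel[[j]]$config$max_cross_alignment)
        if (cross_similarity(cand$sequence, panel[[j]]$sequence) > lim ||
            longest_shared_substring(cand$sequence, panel[[j]]$sequence) > lim) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        panel[[i]] <- cand
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      stop("design failed: panel member ", ids[i],
           " could not satisfy the between-sequence screen after ",
           max_regen, " regenerations", call. = FALSE)
    }
  }
  names(panel) <- ids
  panel
}
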