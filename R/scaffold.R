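#' Primer set
#'
#' A named forward/reverse primer pair targeting one rRNA-operon region.
#'
#' @param name locus label, e.g. `"SSU-V9"`.
#' @param forward,reverse primer sequences (IUPAC alphabet, written 5'->3').
#' @return a `primer_set` list.
#' @export
primer_set <- function(name, forward, reverse) {
  stopifnot(is.character(name), nzchar(name))
  forward <- assert_dna(forward, what = "forward primer", allow_iupac = TRUE)
  reverse <- assert_dna(reverse, what = "reverse primer", allow_iupac = TRUE)
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_set")
}

#' Locate primer binding sites on a reference
#'
#' Finds all matches of a primer on the forward strand and of its reverse
#' complement on the reverse strand, allowing IUPAC-degenerate bases and up
#' to `max_mismatch` mismatches. Conserved blocks of a mimic construct are
#' anchored at these sites.
#'
#' @param ref named character scalar (or plain string) with the reference
#'   sequence, A/C/G/T/N alphabet.
#' @param primer IUPAC primer string (length >= 10).
#' @param max_mismatch allowed mismatches (default 0).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `strand` (`"+"`/`"-"`) and `mismatches`, sorted by `start`; zero rows if
#'   the primer is absent.
#' @export
locate_primer_sites <- function(ref, primer, max_mismatch = 0L) {
  primer <- assert_dna(primer, what = "primer", allow_iupac = TRUE)
  if (nchar(primer) < 10L) stop("primer must be >= 10 bp", call. = FALSE)
  subject <- Biostrings::DNAString(toupper(as.character(ref)[1]))
  hit_frame <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mismatch, fixed = FALSE)
    if (!length(m)) {
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), mismatches = integer(0)))
    }
    mm <- vapply(seq_along(m), function(i) {
      Biostrings::neditAt(Biostrings::DNAString(pat), subject,
                          at = BiocGenerics::start(m)[i], fixed = FALSE)
    }, integer(1))
    data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
               strand = strand, mismatches = mm)
  }
  out <- rbind(hit_frame(primer, "+"), hit_frame(revcomp(primer), "-"))
  out[order(out$start), , drop = FALSE]
}

#' Substitution plan for a mimic construct
#'
#' An ordered recipe alternating conserved anchors (a primer whose unique
#' binding site on a reference, extended by `flank` bp toward the amplicon
#' interior, is retained verbatim) and artificial inserts (IDs into a
#' designed panel). Anchors may draw on different references, which is how a
#' bacterial SSU-V4 cassette is appended to a fungal operon scaffold.
#'
#' @param id construct identifier.
#' @param steps list of steps, each created by [plan_conserved()] or
#'   [plan_artificial()].
#' @return a `mimic_plan` list.
#' @export
mimic_plan <- function(id, steps) {
  stopifnot(is.character(id), nzchar(id), is.list(steps), length(steps) >= 1)
  types <- vapply(steps, function(s) s$type, character(1))
  stopifnot(all(types %in% c("conserved", "artificial")))
  structure(list(id = id, steps = steps), class = "mimic_plan")
}

#' @rdname mimic_plan
#' @param ref id of the reference operon the anchor lives on.
#' @param primer name of the anchoring primer set entry (see `primers`
#'   argument of [build_mimic()]).
#' @param which `"forward"` or `"reverse"`: which primer of the set anchors
#'   this block.
#' @param flank bp of natural sequence retained beyond the primer footprint,
#'   toward the amplicon interior (default 20).
#' @export
plan_conserved <- function(ref, primer, which = c("forward", "reverse"),
                           flank = 20L) {
  which <- match.arg(which)
  list(type = "conserved", ref = ref, primer = primer, which = which,
       flank = as.integer(flank))
}

#' @rdname mimic_plan
#' @param art_id id of an artificial sequence in the designed panel.
#' @export
plan_artificial <- function(art_id) {
  list(type = "artificial", art_id = art_id)
}

#' Build a mimic construct from a substitution plan
#'
#' Assembles a synthetic operon: conserved blocks are extracted verbatim from
#' the reference at unique primer-anchored sites, and the intervening
#' variable regions are replaced by designed artificial sequences. The
#' result records every segment with its label, origin and coordinates on
#' the construct (1-based inclusive), so the layout can be exported as GFF3
#' and round-tripped exactly.
#'
#' @param refs named character vector (or list) of reference operon
#'   sequences; names are the ids used by `plan_conserved(ref = ...)`.
#' @param primers data.frame with columns `name`, `forward`, `reverse` (as
#'   from [default_primer_sets()]`$primers`), or a list of [primer_set()]s.
#' @param artificial list of `artificial_sequence` objects (or a named
#'   character vector of sequences).
#' @param plan a [mimic_plan()].
#' @param max_mismatch mismatches allowed when anchoring primers (default 0).
#' @return a `mimic_construct`: list with `id`, `segments` (data.frame:
#'   `label`, `origin`, `start`, `end`, `seq`) and `sequence`.
#' @export
build_mimic <- function(refs, primers, artificial, plan, max_mismatch = 0L) {
  stopifnot(inherits(plan, "mimic_plan"))
  refs <- resolve_refs(refs)
  primer_tab <- resolve_primers(primers)
  art_seqs <- resolve_artificial(artificial)
  pieces <- lapply(plan$steps, function(step) {
    if (step$type == "artificial") {
      seq <- art_seqs[[step$art_id]]
      if (is.null(seq)) {
        stop("artificial sequence '", step$art_id, "' not provided",
             call. = FALSE)
      }
      return(list(label = "artificial", origin = step$art_id, seq = seq))
    }
    ref_seq <- refs[[step$ref]]
    if (is.null(ref_seq)) {
      stop("reference '", step$ref, "' not provided", call. = FALSE)
    }
    row <- primer_tab[primer_tab$name == step$primer, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("primer set '", step$primer, "' not found", call. = FALSE)
    }
    pseq <- if (step$which == "forward") row$forward else row$reverse
    sites <- locate_primer_sites(ref_seq, pseq, max_mismatch = max_mismatch)
    if (nrow(sites) == 0L) {
      stop("primer ", step$primer, " (", step$which, ") has no site on ",
           step$ref, call. = FALSE)
    }
    if (nrow(sites) > 1L) {
      stop("primer ", step$primer, " (", step$which, ") is ambiguous on ",
           step$ref, ": ", nrow(sites), " sites", call. = FALSE)
    }
    n <- nchar(ref_seq)
    # the amplicon interior lies 3' of the primer: rightward for a primer
    # bound on the + strand, leftward for one bound on the - strand
    if (sites$strand == "+") {
      from <- sites$start
      to <- min(n, sites$end + step$flank)
    } else {
      from <- max(1L, sites$start - step$flank)
      to <- sites$end
    }
    list(label = "conserved",
         origin = paste0(step$ref, ":", from, "-", to, "(", sites$strand, ")"),
         seq = substr(ref_seq, from, to))
  })
  seqs <- vapply(pieces, `[[`, character(1), "seq")
  ends <- cumsum(nchar(seqs))
  segments <- data.frame(
    label = vapply(pieces, `[[`, character(1), "label"),
    origin = vapply(pieces, `[[`, character(1), "origin"),
    start = c(1L, head(ends, -1L) + 1L),
    end = ends,
    seq = seqs,
    stringsAsFactors = FALSE
  )
  structure(list(id = plan$id, segments = segments,
                 sequence = paste(seqs, collapse = "")),
            class = "mimic_construct")
}

resolve_refs <- function(refs) {
  if (is.character(refs) && is.null(names(refs)) && length(refs) == 1L) {
    refs <- c(ref = refs)
  }
  refs <- as.list(refs)
  stopifnot(length(refs) >= 1, !is.null(names(refs)))
  lapply(refs, function(s) assert_dna(s, what = "reference", allow_iupac = TRUE))
}

resolve_primers <- function(primers) {
  if (is.data.frame(primers)) {
    stopifnot(all(c("name", "forward", "reverse") %in% names(primers)))
    return(primers)
  }
  if (inherits(primers, "primer_set")) primers <- list(primers)
  do.call(rbind, lapply(primers, function(p) {
    data.frame(name = p$name, forward = p$forward, reverse = p$reverse,
               stringsAsFactors = FALSE)
  }))
}

resolve_artificial <- function(artificial) {
  if (is.character(artificial)) return(as.list(artificial))
  if (inherits(artificial, "artificial_sequence")) artificial <- list(artificial)
  out <- lapply(artificial, function(a) {
    if (inherits(a, "artificial_sequence")) a$sequence else as.character(a)
  })
  ids <- vapply(artificial, function(a) {
    if (inherits(a, "artificial_sequence")) a$id else NA_character_
  }, character(1))
  if (is.null(names(out)) || any(!nzchar(names(out)))) names(out) <- ids
  out
}

#' @export
print.mimic_construct <- function(x, ...) {
  cat("Mimic construct", x$id, "-", nchar(x$sequence), "bp,",
      nrow(x$segments), "segments\n")
  print(x$segments[, c("label", "origin", "start", "end")])
  invisible(x)
}

#' In-silico PCR on a mimic construct
#'
#' Predicts amplicons for a primer set: every pairing of a forward-primer
#' site (+ strand) upstream of a reverse-primer site (- strand) within
#' `max_len` yields one amplicon, primers included.
#'
#' @param construct a `mimic_construct` (or plain DNA string).
#' @param primers a [primer_set()].
#' @param max_mismatch mismatches allowed per primer site.
#' @param max_len maximum amplicon length considered productive.
#' @return data.frame with `primer_set`, `start`, `end`, `length`,
#'   `sequence`; zero rows when no productive orientation exists.
#' @export
in_silico_pcr <- function(construct, primers, max_mismatch = 0L,
                          max_len = 5000L) {
  stopifnot(inherits(primers, "primer_set"))
  seq <- if (inherits(construct, "mimic_construct")) {
    construct$sequence
  } else as.character(construct)
  fwd <- locate_primer_sites(seq, primers$forward, max_mismatch)
  fwd <- fwd[fwd$strand == "+", , drop = FALSE]
  rev <- locate_primer_sites(seq, primers$reverse, max_mismatch)
  rev <- rev[rev$strand == "-", , drop = FALSE]
  out <- data.frame(primer_set = character(0), start = integer(0),
                    end = integer(0), length = integer(0),
                    sequence = character(0))
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      if (rev$end[j] > fwd$start[i] &&
          rev$start[j] > fwd$end[i] &&
          rev$end[j] - fwd$start[i] + 1L <= max_len) {
        len <- rev$end[j] - fwd$start[i] + 1L
        out <- rbind(out, data.frame(
          primer_set = primers$name, start = fwd$start[i], end = rev$end[j],
          length = len, sequence = substr(seq, fwd$start[i], rev$end[j])))
      }
    }
  }
  out
}

#' Segment annotation of a construct as GRanges
#'
#' @param construct a `mimic_construct`.
#' @return a [GenomicRanges::GRanges] with one range per segment (`type`
#'   column: conserved/artificial, `origin` column), on seqname
#'   `construct$id`.
#' @export
mimic_segments_granges <- function(construct) {
  stopifnot(inherits(construct, "mimic_construct"))
  seg <- construct$segments
  gr <- GenomicRanges::GRanges(
    seqnames = construct$id,
    ranges = IRanges::IRanges(start = seg$start, end = seg$end),
    strand = "+"
  )
  S4Vectors::mcols(gr)$type <- seg$label
  S4Vectors::mcols(gr)$origin <- seg$origin
  GenomeInfoDb::seqlengths(gr) <- nchar(construct$sequence)
  gr
}
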