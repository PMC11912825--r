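#' Read and write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] exchanging plain named character vectors,
#' validated against the DNA alphabet. Output wraps at 80 columns;
#' `read_fasta(write_fasta(x))` is the identity on canonicalized
#' (uppercase, unwrapped) content.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta`: named character vector. `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  # read permissively, then validate: readDNAStringSet would silently drop
  # invalid letters instead of failing
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    assert_dna(seqs[[i]], what = paste0("record ", names(seqs)[i]),
               allow_iupac = TRUE)
  }
  seqs
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Read and write count tables as TSV
#'
#' Features in rows, samples in columns, first column `feature_id`, header
#' row of sample ids. Counts must parse as non-negative integers; anything
#' else is rejected with the offending location.
#'
#' @param path file path.
#' @param table a [count_table()].
#' @param feature_seqs optional named character vector attached to the
#'   result.
#' @return `read_counts_tsv`: a [count_table()]. `write_counts_tsv`:
#'   `path`, invisibly.
#' @export
read_counts_tsv <- function(path, feature_seqs = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count TSV needs feature ids plus >= 1 sample",
                          call. = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(mat))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer count at ", path, " row ", bad[1, 1] + 1L,
         " (feature ", ids[bad[1, 1]], "), column ",
         colnames(mat)[bad[1, 2]], call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(mat))
  count_table(num, feature_seqs)
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(feature_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer table
#'
#' TSV with columns `name`, `forward`, `reverse`; sequences validated as
#' IUPAC DNA.
#'
#' @param path file path.
#' @return data.frame usable as the `primers` argument of [build_mimic()].
#' @export
read_primer_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "forward", "reverse")
  if (!all(need %in% names(df))) {
    stop("primer TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    df$forward[i] <- assert_dna(df$forward[i], "forward primer",
                                allow_iupac = TRUE)
    df$reverse[i] <- assert_dna(df$reverse[i], "reverse primer",
                                allow_iupac = TRUE)
  }
  df
}

#' Read spike-in metadata
#'
#' TSV with columns `sample`, `mimic`, `copies`, `sample_amount`,
#' `amount_unit`, `amount_basis`.
#'
#' @param path file path.
#' @return a [spike_config()].
#' @export
read_spike_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  spike_config(df)
}

#' Write construct segment annotation as GFF3
#'
#' One feature per segment (conserved or artificial), 1-based inclusive
#' coordinates per the GFF3 standard, via [rtracklayer::export()].
#'
#' @param construct a `mimic_construct` (or list of them).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(construct, path) {
  if (inherits(construct, "mimic_construct")) construct <- list(construct)
  grl <- lapply(construct, mimic_segments_granges)
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write per-sequence screening reports as TSV
#'
#' One row per designed sequence, one column per screen metric.
#'
#' @param panel list of `artificial_sequence` objects (from
#'   [design_panel()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(panel, path) {
  rows <- lapply(panel, function(a) {
    s <- a$screen
    data.frame(id = a$id, length = nchar(a$sequence),
               gc = round(a$gc, 4),
               max_homopolymer_run = s$max_homopolymer_run,
               max_direct_repeat = s$max_direct_repeat,
               max_inverted_repeat = s$max_inverted_repeat,
               max_gc_window_deviation = round(s$max_gc_window_deviation, 3),
               prohibited_kmer_hits = s$prohibited_kmer_hits,
               composition_imbalance = round(s$composition_imbalance, 4),
               passed = s$passed, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Records the resolved configuration and seed of a run so it can be
#' reproduced bit for bit.
#'
#' @param config a list (e.g. a [design_config()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}
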