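#' @useDynLib spikemimic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm nls resid rmultinom rlnorm runif setNames
#'   complete.cases cor sd median
#' @importFrom utils read.delim write.table
#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> the set of bases each matches
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' IUPAC-aware reverse complementation of a plain character string.
#'
#' @param seq character scalar over the IUPAC DNA alphabet.
#' @return character scalar.
#' @export
#' @examples
#' revcomp("AAGCTT")  # palindromic HindIII site
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  paste(rev(seq_chars(comp)), collapse = "")
}

#' GC fraction of a DNA string
#'
#' @param seq character scalar over A/C/G/T.
#' @return fraction in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  chars <- seq_chars(seq)
  mean(chars %in% c("G", "C"))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

assert_dna <- function(seq, what = "sequence", allow_iupac = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop(what, " must be a nonempty character scalar", call. = FALSE)
  }
  alphabet <- if (allow_iupac) names(IUPAC_MAP) else DNA_BASES
  chars <- seq_chars(toupper(seq))
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad)) {
    stop(what, " contains invalid characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(toupper(seq))
}

# all substrings of length k, in order of start position
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (k > n) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# deterministic child seed derived from a user seed and a stream label
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
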