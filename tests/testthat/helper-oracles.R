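# Independent brute-force oracles for the designer screens. Deliberately
# written with different algorithms than the package implementations:
# position loops and shift-scans instead of k-mer sets and binary search.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_homopolymer <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  best <- 1L
  run <- 1L
  for (i in seq_along(chars)[-1]) {
    run <- if (chars[i] == chars[i - 1]) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

# longest run of agreement between the sequence and itself at every shift
# (a direct repeat of length L at distance d is a TRUE-run of length L)
oracle_direct_repeat <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  best <- 0L
  for (d in seq_len(n - 1L)) {
    eq <- chars[seq_len(n - d)] == chars[seq_len(n - d) + d]
    r <- rle(eq)
    hit <- r$lengths[r$values]
    if (length(hit)) best <- max(best, hit)
  }
  best
}

# longest common substring of the sequence and its reverse complement,
# scanned at every relative offset
oracle_inverted_repeat <- function(seq) {
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(revcomp(seq), "")[[1]]
  n <- length(a)
  best <- 0L
  for (off in seq(-(n - 1L), n - 1L)) {
    ia <- max(1L, 1L + off):min(n, n + off)
    eq <- a[ia] == b[ia - off]
    r <- rle(eq)
    hit <- r$lengths[r$values]
    if (length(hit)) best <- max(best, hit)
  }
  best
}

oracle_gc_windows <- function(seq, window, step, reference_gc) {
  n <- nchar(seq)
  starts <- unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
  devs <- vapply(starts, function(s) {
    w <- substr(seq, s, s + window - 1L)
    gc <- sum(strsplit(w, "")[[1]] %in% c("G", "C")) / window
    abs(gc - reference_gc)
  }, numeric(1))
  100 * max(devs)
}

# IUPAC code -> regex character class
iupac_regex <- function(p) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[GC]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
               D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(classes[strsplit(p, "")[[1]]], collapse = "")
}

# count positions matching any primer-derived k-mer, by overlapping regex
# scans (one lookahead regex per primer window and orientation)
oracle_prohibited <- function(seq, primers, k) {
  n <- nchar(seq)
  hit <- logical(n - k + 1L)
  for (p in primers) {
    for (orient in c(p, revcomp(p))) {
      for (s in seq_len(nchar(orient) - k + 1L)) {
        pat <- paste0("(?=", iupac_regex(substr(orient, s, s + k - 1L)), ")")
        m <- gregexpr(pat, seq, perl = TRUE)[[1]]
        if (m[1] != -1L) hit[m[m <= length(hit)]] <- TRUE
      }
    }
  }
  sum(hit)
}

# pure-R affine-gap local alignment (Gotoh), lexicographic (score, columns);
# mirrors the scoring contract but shares no code with the C++ kernel
oracle_local_align <- function(a, b, match = 1, mismatch = -3,
                               gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e30
  H <- matrix(0, n + 1, m + 1); Hl <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1); El <- matrix(0, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1); Fl <- matrix(0, n + 1, m + 1)
  best <- 0; best_len <- 0
  pick <- function(s1, l1, s2, l2) {
    if (s1 > s2 || (s1 == s2 && l1 >= l2)) c(s1, l1) else c(s2, l2)
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      e <- pick(H[i, j - 1] - gap_open - gap_ext, Hl[i, j - 1] + 1,
                E[i, j - 1] - gap_ext, El[i, j - 1] + 1)
      E[i, j] <- e[1]; El[i, j] <- e[2]
      f <- pick(H[i - 1, j] - gap_open - gap_ext, Hl[i - 1, j] + 1,
                F[i - 1, j] - gap_ext, Fl[i - 1, j] + 1)
      F[i, j] <- f[1]; Fl[i, j] <- f[2]
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      h <- pick(H[i - 1, j - 1] + s, Hl[i - 1, j - 1] + 1, 0, 0)
      h <- pick(h[1], h[2], E[i, j], El[i, j])
      h <- pick(h[1], h[2], F[i, j], Fl[i, j])
      if (h[1] < 0) h <- c(0, 0)
      H[i, j] <- h[1]; Hl[i, j] <- h[2]
      upd <- pick(best, best_len, h[1], h[2])
      best <- upd[1]; best_len <- upd[2]
    }
  }
  list(score = best, length = best_len)
}

# Biostrings local alignment score with the same scoring scheme -- the
# library cross-check for the C++ kernel
biostrings_local_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  Biostrings::score(aln)
}
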