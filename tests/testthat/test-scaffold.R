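make_toy_ref <- function(seed = 5) {
  set.seed(seed)
  p <- default_primer_sets()$primers
  fwd <- p$forward[p$name == "SSU-V9"]
  rev <- p$reverse[p$name == "LSU-D1D2"]
  list(
    ref = paste0(random_seq(100), fwd, random_seq(800), revcomp(rev),
                 random_seq(100)),
    fwd = fwd, rev = rev, primers = p
  )
}

test_that("primer sites are located on both strands with exact coordinates", {
  toy <- make_toy_ref()
  hits_f <- locate_primer_sites(toy$ref, toy$fwd)
  expect_identical(nrow(hits_f), 1L)
  expect_identical(hits_f$start, 101L)
  expect_identical(hits_f$strand, "+")
  expect_identical(hits_f$mismatches, 0L)
  hits_r <- locate_primer_sites(toy$ref, toy$rev)
  expect_identical(nrow(hits_r), 1L)
  expect_identical(hits_r$strand, "-")
  # absent primer -> empty frame
  expect_identical(nrow(locate_primer_sites(toy$ref, "GGGGGGCCCCCCAAAAATTTTT")),
                   0L)
  # degenerate base matches its expansions
  site <- substr(toy$ref, 101, 116)
  deg <- paste0(substr(site, 1, 8), "N", substr(site, 10, 16))
  expect_identical(nrow(locate_primer_sites(toy$ref, deg)), 1L)
})

test_that("build_mimic produces a tiling conserved|artificial|conserved construct", {
  toy <- make_toy_ref()
  art <- assemble_sequence(design_config(target_length = 300, rng_seed = 3),
                           id = "artA")
  plan <- mimic_plan("toy1", list(
    plan_conserved("ref1", "SSU-V9", "forward"),
    plan_artificial("artA"),
    plan_conserved("ref1", "LSU-D1D2", "reverse")
  ))
  con <- build_mimic(c(ref1 = toy$ref), toy$primers, list(art), plan)
  expect_identical(con$segments$label, c("conserved", "artificial", "conserved"))
  # segments tile the construct without gaps
  expect_identical(con$segments$start,
                   c(1L, head(con$segments$end, -1) + 1L))
  # round trip: concatenated segments reproduce the full sequence
  expect_identical(paste(con$segments$seq, collapse = ""), con$sequence)
  # conserved segments are verbatim reference substrings
  for (i in which(con$segments$label == "conserved")) {
    expect_true(grepl(con$segments$seq[i], toy$ref, fixed = TRUE))
  }
  # artificial segment is the designed sequence
  expect_identical(con$segments$seq[2], art$sequence)
  # coordinates re-extract each segment from the construct
  for (i in seq_len(nrow(con$segments))) {
    expect_identical(substr(con$sequence, con$segments$start[i],
                            con$segments$end[i]),
                     con$segments$seq[i])
  }
})

test_that("ambiguous or missing primer sites are hard errors", {
  toy <- make_toy_ref()
  art <- assemble_sequence(design_config(target_length = 100, rng_seed = 4),
                           id = "artA")
  dup_ref <- paste0(toy$ref, toy$ref)  # every primer now has two sites
  plan <- mimic_plan("bad", list(
    plan_conserved("ref1", "SSU-V9", "forward"),
    plan_artificial("artA")
  ))
  expect_error(build_mimic(c(ref1 = dup_ref), toy$primers, list(art), plan),
               "ambiguous")
  plan2 <- mimic_plan("bad2", list(
    plan_conserved("ref1", "ITS1", "forward"),
    plan_artificial("artA")
  ))
  expect_error(build_mimic(c(ref1 = toy$ref), toy$primers, list(art), plan2),
               "no site")
})

test_that("in_silico_pcr predicts amplicons with exact arithmetic", {
  toy <- make_toy_ref()
  art <- assemble_sequence(design_config(target_length = 300, rng_seed = 3),
                           id = "artA")
  plan <- mimic_plan("toy1", list(
    plan_conserved("ref1", "SSU-V9", "forward"),
    plan_artificial("artA"),
    plan_conserved("ref1", "LSU-D1D2", "reverse")
  ))
  con <- build_mimic(c(ref1 = toy$ref), toy$primers, list(art), plan)
  ps <- primer_set("V9-D1D2", toy$fwd, toy$rev)
  amp <- in_silico_pcr(con, ps)
  expect_identical(nrow(amp), 1L)
  # construct is exactly primer-to-primer here: amplicon spans everything
  expect_identical(amp$length, nchar(con$sequence))
  expect_identical(amp$sequence, con$sequence)
  # non-productive orientation: swap the primers
  expect_identical(nrow(in_silico_pcr(con, primer_set("swap", toy$rev, toy$fwd))),
                   0L)
  # amplicon interior (artificial part) has no prohibited primer k-mers
  expect_identical(
    scan_prohibited_kmers(con$segments$seq[2],
                          default_primer_sets()$all_primers, k = 8), 0L)
})

test_that("cross-domain cassette adds a bacterial-primer-amplifiable region", {
  toy <- make_toy_ref()
  p <- toy$primers
  v4f <- p$forward[p$name == "SSU-V4"]
  v4r <- p$reverse[p$name == "SSU-V4"]
  set.seed(6)
  # E. coli-style 16S fragment: V4 conserved flanks around a variable core
  ecoli <- paste0(random_seq(50), "GTGCCAGCAGCCGCGGTAA", random_seq(250),
                  revcomp("GGACTACTCGGGTATCTAAT"), random_seq(50))
  art1 <- assemble_sequence(design_config(target_length = 200, rng_seed = 8),
                            id = "artA")
  art2 <- assemble_sequence(design_config(target_length = 150, rng_seed = 9),
                            id = "artB")
  plan <- mimic_plan("cross1", list(
    plan_conserved("sc", "SSU-V9", "forward"),
    plan_artificial("artA"),
    plan_conserved("sc", "LSU-D1D2", "reverse"),
    plan_conserved("ec", "SSU-V4", "forward"),
    plan_artificial("artB"),
    plan_conserved("ec", "SSU-V4", "reverse")
  ))
  con <- build_mimic(c(sc = toy$ref, ec = ecoli), p,
                     list(art1, art2), plan)
  amp_v4 <- in_silico_pcr(con, primer_set("SSU-V4", v4f, v4r))
  expect_identical(nrow(amp_v4), 1L)
  # fungal-only construct is not amplifiable by the bacterial set
  plan_f <- mimic_plan("fungal", list(
    plan_conserved("sc", "SSU-V9", "forward"),
    plan_artificial("artA"),
    plan_conserved("sc", "LSU-D1D2", "reverse")
  ))
  con_f <- build_mimic(c(sc = toy$ref), p, list(art1), plan_f)
  expect_identical(nrow(in_silico_pcr(con_f, primer_set("SSU-V4", v4f, v4r))),
                   0L)
})

test_that("GFF3 export round-trips segment coordinates", {
  toy <- make_toy_ref()
  art <- assemble_sequence(design_config(target_length = 150, rng_seed = 2),
                           id = "artA")
  plan <- mimic_plan("toy1", list(
    plan_conserved("ref1", "SSU-V9", "forward"),
    plan_artificial("artA"),
    plan_conserved("ref1", "LSU-D1D2", "reverse")
  ))
  con <- build_mimic(c(ref1 = toy$ref), toy$primers, list(art), plan)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(con, gff)
  back <- rtracklayer::import(gff)
  expect_identical(length(back), nrow(con$segments))
  for (i in seq_along(back)) {
    expect_identical(
      substr(con$sequence, BiocGenerics::start(back)[i],
             BiocGenerics::end(back)[i]),
      con$segments$seq[i])
  }
  expect_identical(as.character(back$type), con$segments$label)
})
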