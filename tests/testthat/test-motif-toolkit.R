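# SLiM pattern parsing, scanning, exon mapping, acquisition matrix and the
# family-membership rule.

cornr <- parse_slim_pattern("L/I.x.x.I/H.I.x.x.x.I/L", "CoRNR")

test_that("pattern parsing handles wildcards, alternatives and errors", {
  expect_length(cornr$positions, 9)
  expect_equal(cornr$constrained, c(1L, 4L, 5L, 9L))
  expect_equal(cornr$positions[[1]], c("L", "I"))
  expect_equal(cornr$positions[[4]], c("I", "H"))
  expect_equal(cornr$positions[[5]], "I")
  expect_equal(cornr$positions[[9]], c("I", "L"))
  expect_equal(cornr$key_positions, 9L)  # most C-terminal constrained

  single <- parse_slim_pattern("x", "w")
  expect_length(single$positions, 1)
  expect_null(single$positions[[1]])
  expect_error(parse_slim_pattern("L//I", "bad"), "malformed")
  expect_error(parse_slim_pattern("L.B", "bad"), "non-amino-acid")
  expect_error(parse_slim_pattern("L..I", "bad"), "empty token")
  expect_error(parse_slim_pattern("L/I.x", "bad", key_positions = 2),
               "key_positions")
})

test_that("pattern files round-trip name, spec and key positions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "CoRNR\tL/I.x.x.I/H.I.x.x.x.I/L\t1,9",
               "SHARP\tG.P.S/T.L/I.x.x.L"), f)
  pats <- read_slim_patterns(f)
  expect_named(pats, c("CoRNR", "SHARP"))
  expect_equal(pats$CoRNR$key_positions, c(1L, 9L))
  expect_equal(pats$SHARP$key_positions, 7L)
  expect_length(default_slim_patterns(), 2)
})

test_that("scanning finds complete and partial motif instances", {
  hits <- scan_protein("AALAAHIAAALAA", cornr)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2L)
  expect_equal(hits$status, "complete")
  expect_equal(hits$end - hits$start, 9L)

  # terminal-residue mismatch only: partial at the key position
  part <- scan_protein("LAAHIAAAK", cornr)
  expect_equal(part$status, "partial")
  expect_equal(part$mismatched_positions[[1]], 9L)
  expect_equal(nrow(scan_protein("LAAHIAAAK", cornr, allow_partial = FALSE)), 0)

  # single mismatch at a non-key constrained position: no hit
  expect_equal(nrow(scan_protein("KAAHIAAAL", cornr)), 0)
  # too-short protein: empty result, no error
  expect_equal(nrow(scan_protein("LAAH", cornr)), 0)
})

test_that("scanning matches a brute-force window check on random proteins", {
  withr::with_seed(7, {
    alph <- c("L", "I", "H", "A", "K")  # enriched so hits actually occur
    n_hits <- 0
    for (i in 1:300) {
      prot <- random_protein(sample(9:200, 1), alphabet = alph)
      got <- scan_protein(prot, cornr)
      want <- brute_scan(prot, cornr)
      expect_equal(got$start, want$start)
      expect_equal(got$status, want$status)
      n_hits <- n_hits + nrow(want)
    }
    expect_gt(n_hits, 100)  # the comparison was not vacuous
  })
})

test_that("hits map onto encoding exons and back to the same peptide", {
  fx <- toy_gene_fixture()
  prot <- gene_protein(fx$gene, fx$genome)$protein
  hit <- scan_protein(prot, cornr)
  expect_equal(nrow(hit), 1)

  mapped <- map_hit_to_exons(hit, fx$gene, fx$genome)
  # the motif spans the junction: two exons, sub-intervals partition 27 nt
  expect_equal(mapped$exon_label, c("1", "2"))
  expect_equal(sum(mapped$genomic_end - mapped$genomic_start), 27)

  # extraction oracle: translating the mapped nucleotides reproduces the
  # matched peptide
  g <- fx$genome$seq[1]
  nt <- paste(substring(g, mapped$genomic_start + 1, mapped$genomic_end),
              collapse = "")
  expect_equal(translate_cds(nt)$protein,
               substr(prot, hit$start + 1, hit$end))

  # same on the minus strand
  fm <- toy_gene_fixture(strand = "-")
  hitm <- scan_protein(gene_protein(fm$gene, fm$genome)$protein, cornr)
  mappedm <- map_hit_to_exons(hitm, fm$gene, fm$genome)
  expect_equal(sum(mappedm$genomic_end - mappedm$genomic_start), 27)
  gm <- fm$genome$seq[1]
  # rows are in transcription order: reverse-complement each sub-interval
  # and concatenate in that order
  ntm <- paste(
    vapply(seq_len(nrow(mappedm)), function(i) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substring(gm, mappedm$genomic_start[i] + 1, mappedm$genomic_end[i]))))
    }, character(1)),
    collapse = ""
  )
  expect_equal(ntm, nt)

  # a hit wholly inside one exon maps to a single label
  hit1 <- tibble::tibble(start = 0L, end = 2L)
  m1 <- map_hit_to_exons(hit1, fx$gene, fx$genome)
  expect_equal(m1$exon_label, "1")
  expect_error(map_hit_to_exons(tibble::tibble(start = 0L, end = 100L),
                                fx$gene, fx$genome), "beyond")
})

test_that("acquisition matrix applies the complete-dominates-partial rule", {
  hits <- tibble::tibble(
    species = c("hemi", "hemi", "hemi", "vert", "vert"),
    pattern_name = c("M1", "M2", "M5", "M1", "M1"),
    status = c("complete", "complete", "partial", "partial", "complete")
  )
  mat <- motif_acquisition_matrix(hits, c("M1", "M2", "M5"))
  hemi <- mat[mat$species == "hemi", ]
  expect_equal(unlist(hemi[, c("M1", "M2", "M5")], use.names = FALSE),
               c("complete", "complete", "partial"))
  # both complete and partial present -> complete wins
  expect_equal(mat$M1[mat$species == "vert"], "complete")
  expect_equal(mat$M5[mat$species == "vert"], "absent")

  empty <- motif_acquisition_matrix(hits[0, ], c("M1", "M2"),
                                    species = "none")
  expect_equal(unlist(empty[, c("M1", "M2")], use.names = FALSE),
               c("absent", "absent"))
})

test_that("family membership needs two CoRNR boxes, ordered SHARP and two SANTs", {
  mk <- function(names, starts, status = "complete") {
    tibble::tibble(pattern_name = names, start = starts,
                   end = starts + 9L, status = status)
  }
  good <- mk(c("CoRNR", "CoRNR", "SHARP"), c(10, 40, 90))
  expect_true(validate_family_membership(good, sant_count = 2)$accept)

  out_of_order <- mk(c("CoRNR", "SHARP", "CoRNR"), c(10, 40, 90))
  res <- validate_family_membership(out_of_order, sant_count = 2)
  expect_false(res$accept)
  expect_equal(res$reasons, "order")

  res <- validate_family_membership(good, sant_count = 1)
  expect_false(res$accept)
  expect_equal(res$reasons, "SANT")

  one_box <- mk(c("CoRNR", "SHARP"), c(10, 90))
  expect_true("CoRNR" %in% validate_family_membership(one_box, 2)$reasons)
  # partial CoRNR boxes do not count towards the two
  partials <- mk(c("CoRNR", "CoRNR", "SHARP"), c(10, 40, 90),
                 status = c("partial", "complete", "complete"))
  expect_false(validate_family_membership(partials, 2)$accept)
  no_sharp <- mk(c("CoRNR", "CoRNR"), c(10, 40))
  expect_true("SHARP" %in% validate_family_membership(no_sharp, 2)$reasons)
})
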