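# Sequence I/O, gene models, splicing and translation.

test_that("FASTA reading normalises case, preserves order and checks the alphabet", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt", ">b desc", "GGGG", ">c", "ttaa"), f)
  recs <- read_sequences(f)
  expect_equal(recs$id, c("a", "b", "c"))
  expect_equal(recs$seq[1], "ACGT")

  writeLines(c(">bad", "ACJT"), f)
  expect_error(read_sequences(f), "bad.*'J' at position 3")
  writeLines(c(">r", "ACGU"), f)
  expect_error(read_sequences(f), "'U'")
  expect_equal(read_sequences(f, rna_to_dna = TRUE)$seq, "ACGT")
  writeLines(character(0), f)
  expect_error(read_sequences(f))
})

test_that("gene_model enforces its invariants", {
  ex <- tibble::tibble(label = c("1", "2"), start = c(0, 10), end = c(5, 20))
  expect_s3_class(gene_model("g", "c", "+", ex), "gene_model")
  expect_error(gene_model("g", "c", "+", dplyr::mutate(ex, end = c(12, 20))),
               "overlap")
  expect_error(gene_model("g", "c", "+", dplyr::mutate(ex, label = c("1", "1"))),
               "unique")
  expect_error(gene_model("g", "c", "-", ex), "transcription order")
  expect_s3_class(gene_model("g", "c", "-", ex[2:1, ]), "gene_model")
  ex$internal_donors <- list(integer(0), 12L)
  expect_error(gene_model("g", "c", "+", ex), "out of range")
})

test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t4\t40\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t4\t40\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\t.\texon\t4\t9\t.\t+\t.\tID=e1;Parent=g1.t1;label=37",
    "chr1\t.\texon\t20\t40\t.\t+\t.\tID=e2;Parent=g1.t1;label=38",
    "chr1\t.\tCDS\t4\t9\t.\t+\t1\tID=c1;Parent=g1.t1"
  ), f)
  g <- read_gene_models(f)[["g1"]]
  expect_equal(g$exons$start, c(3L, 19L))
  expect_equal(g$exons$end, c(9L, 40L))
  expect_equal(g$cds_start_phase, 1L)

  # minus-strand exons come back in transcription order
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t4\t40\t.\t-\t.\tID=g1",
    "chr1\t.\texon\t4\t9\t.\t-\t.\tID=e1;Parent=g1;label=A",
    "chr1\t.\texon\t20\t40\t.\t-\t.\tID=e2;Parent=g1;label=B"
  ), f)
  g <- read_gene_models(f)[["g1"]]
  expect_equal(g$exons$label, c("B", "A"))

  # write -> read identity, including internal donors and phase, both strands
  for (strand in c("+", "-")) {
    ex <- tibble::tibble(label = c("37", "38"), start = c(10, 100),
                         end = c(70, 160),
                         internal_donors = list(24L, integer(0)))
    if (strand == "-") ex <- ex[2:1, ]
    gm <- gene_model("gX", "chr2", strand, ex, 2L)
    write_gene_models(gm, f)
    back <- read_gene_models(f)[["gX"]]
    expect_equal(back$exons, gm$exons)
    expect_equal(back$cds_start_phase, gm$cds_start_phase)
    expect_equal(back$strand, gm$strand)
  }

  writeLines(c("##gff-version 3", "chr1\t.\tgene\t4\t40\t.\t+\t.\tID=g1"), f)
  expect_error(read_gene_models(f), "exon")
})

test_that("sidecar donor tables merge into gene models", {
  f <- withr::local_tempfile(fileext = ".gff3")
  gm <- gene_model("gY", "chr3", "+",
                   tibble::tibble(label = "37", start = 0, end = 60))
  write_gene_models(gm, f)
  donors <- tibble::tibble(gene_id = "gY", exon_label = "37", cut_index = 33L)
  back <- read_gene_models(f, donors = donors)[["gY"]]
  expect_equal(back$exons$internal_donors[[1]], 33L)
  expect_error(
    read_gene_models(f, donors = tibble::tibble(gene_id = "gY",
                                                exon_label = "99",
                                                cut_index = 3L)),
    "99"
  )
})

test_that("spliced_cds concatenates retained segments under choices", {
  fx <- toy_gene_fixture()
  cds <- spliced_cds(fx$gene, fx$genome)
  expect_equal(nchar(cds), sum(fx$gene$exons$end - fx$gene$exons$start))
  expect_equal(translate_cds(cds, allow_partial = TRUE)$protein, fx$protein)

  ev <- splice_event("d1", "alternative_internal_donor", "1", cut_index = 12)
  short <- spliced_cds(fx$gene, fx$genome, ev, list(d1 = "short"))
  expect_equal(nchar(short), 12 + 27)
  # frame-preserving internal donor: translation outside the excised
  # peptide matches the full-length product
  pshort <- translate_cds(short)$protein
  pfull <- fx$protein
  expect_equal(substr(pshort, 1, 4), substr(pfull, 1, 4))
  expect_equal(substr(pshort, 5, nchar(pshort)),
               substr(pfull, 9, nchar(pfull)))

  ev2 <- splice_event("c2", "cassette_exon", "2")
  expect_equal(spliced_cds(fx$gene, fx$genome, ev2, list(c2 = "excluded")),
               substr(spliced_cds(fx$gene, fx$genome), 1, 24))
  expect_error(spliced_cds(fx$gene, fx$genome, ev, list(nope = "short")),
               "unknown event")
})

test_that("minus-strand genes splice to the same sense CDS", {
  plus <- toy_gene_fixture(strand = "+")
  minus <- toy_gene_fixture(strand = "-")
  expect_equal(spliced_cds(minus$gene, minus$genome),
               spliced_cds(plus$gene, plus$genome))
  ev <- splice_event("d1", "alternative_internal_donor", "1", cut_index = 12)
  expect_equal(spliced_cds(minus$gene, minus$genome, ev, list(d1 = "short")),
               spliced_cds(plus$gene, plus$genome, ev, list(d1 = "short")))
})

test_that("translation follows the standard code and stop semantics", {
  expect_equal(translate_cds("ATGAAATAA"), list(protein = "MK", stopped = TRUE))
  expect_equal(translate_cds("ATGAAA"), list(protein = "MK", stopped = FALSE))
  expect_error(translate_cds("ATGAA"), "multiple of 3")
  expect_equal(translate_cds("ATGAA", allow_partial = TRUE)$protein, "M")
  expect_error(translate_cds("AT"), "at least 3")

  # independent codon-table oracle on random sequences
  withr::with_seed(99, {
    for (i in 1:30) {
      s <- random_dna(300)
      mine <- translate_cds(s)
      ref <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                                no.init.codon = TRUE))
      star <- regexpr("*", ref, fixed = TRUE)
      if (star > 0) {
        expect_true(mine$stopped)
        expect_equal(mine$protein, substr(ref, 1, star - 1))
      } else {
        expect_false(mine$stopped)
        expect_equal(mine$protein, ref)
      }
    }
  })
})

test_that("translation of the spliced CDS is invariant under exon relabeling", {
  fx <- toy_gene_fixture()
  relabeled <- fx$gene
  relabeled$exons$label <- c("x", "y")
  expect_equal(gene_protein(relabeled, fx$genome)$protein,
               gene_protein(fx$gene, fx$genome)$protein)
})
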