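# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by the most naive route available
# (per-window loops, full enumeration, reference library calls) so they
# stay independent of the implementation paths they check.

BASES4 <- c("A", "C", "G", "T")
AA20S <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")
random_protein <- function(n, alphabet = AA20S) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# naive window-by-window motif scan
brute_scan <- function(protein, pattern, allow_partial = TRUE) {
  aa <- strsplit(protein, "")[[1]]
  m <- length(pattern$positions)
  hits <- list()
  for (s in seq_len(max(0, length(aa) - m + 1))) {
    mismatches <- integer(0)
    for (j in pattern$constrained) {
      if (!aa[s + j - 1] %in% pattern$positions[[j]]) {
        mismatches <- c(mismatches, j)
      }
    }
    if (length(mismatches) == 0) {
      hits[[length(hits) + 1]] <- list(start = s - 1L, status = "complete")
    } else if (allow_partial && length(mismatches) == 1 &&
               mismatches %in% pattern$key_positions) {
      hits[[length(hits) + 1]] <- list(start = s - 1L, status = "partial")
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), status = character(0)))
  }
  data.frame(start = vapply(hits, `[[`, integer(1), "start"),
             status = vapply(hits, `[[`, character(1), "status"))
}

# brute-force GT-creation enumeration: try every single-base substitution at
# every position and record dinucleotide starts that become GT (plus, when
# asked, existing GT starts)
brute_gt_positions <- function(exon_seq, include_existing = FALSE) {
  s <- strsplit(exon_seq, "")[[1]]
  L <- length(s)
  found <- list()
  for (p in seq_len(L - 1)) {          # dinucleotide start, 1-based
    d <- paste0(s[p], s[p + 1])
    if (d == "GT") {
      if (include_existing) {
        found[[length(found) + 1]] <- list(pos = p - 1L, off = NA_integer_,
                                           base = NA_character_)
      }
      next
    }
    for (i in c(p, p + 1)) {            # position being mutated
      for (b in setdiff(BASES4, s[i])) {
        mut <- s; mut[i] <- b
        if (paste0(mut[p], mut[p + 1]) == "GT") {
          found[[length(found) + 1]] <- list(pos = p - 1L,
                                             off = as.integer(i - p),
                                             base = b)
        }
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(pos = integer(0), off = integer(0), base = character(0)))
  }
  data.frame(pos = vapply(found, `[[`, integer(1), "pos"),
             off = vapply(found, `[[`, integer(1), "off"),
             base = vapply(found, `[[`, character(1), "base"))
}

# full-enumeration IPF over sequences of length L: returns the fitted joint
# probability for every enumerated sequence (named vector)
ipf_oracle <- function(windows, constraints, pseudocount = 0.5,
                       tol = 1e-10, max_iter = 2000) {
  L <- nchar(windows[1])
  combos <- do.call(expand.grid,
                    c(rep(list(BASES4), L), stringsAsFactors = FALSE))
  # expand.grid varies the FIRST factor fastest; build sequence strings
  seqs <- do.call(paste0, combos[, L:1, drop = FALSE])  # position 1 leftmost
  p <- rep(1 / length(seqs), length(seqs))
  names(p) <- seqs
  pseudo <- 4 * pseudocount
  n <- length(windows)
  proj <- function(seqs, cons) {
    vapply(seqs, function(s) {
      paste(strsplit(s, "")[[1]][cons], collapse = "")
    }, character(1))
  }
  targets <- lapply(constraints, function(cons) {
    k <- length(cons)
    keys <- proj(seqs, cons)
    lv <- sort(unique(keys))
    cnt <- table(factor(proj(windows, cons), levels = lv))
    tg <- (as.numeric(cnt) + pseudo / 4^k) / (n + pseudo)
    stats::setNames(tg, lv)
  })
  keys_by_c <- lapply(constraints, function(cons) proj(seqs, cons))
  for (iter in seq_len(max_iter)) {
    worst <- 0
    for (ci in seq_along(constraints)) {
      keys <- keys_by_c[[ci]]
      marg <- tapply(p, keys, sum)
      tg <- targets[[ci]][names(marg)]
      worst <- max(worst, max(abs(marg - tg)))
      ratio <- ifelse(marg > 0, tg / marg, 1)
      p <- p * unname(ratio[keys])
    }
    if (worst < tol) break
  }
  stats::setNames(p, seqs)
}

# a tiny hand-built two-exon gene on a known contig, with a motif peptide
# spanning the junction when `span_junction`
toy_gene_fixture <- function(span_junction = FALSE, strand = "+") {
  # peptides: exon1 encodes "MKL AAH IA" start of motif; exon2 the rest
  pep1 <- "MKLAAHIA"   # 8 aa -> 24 nt
  pep2 <- "AALGGWSTR"  # 9 aa -> 27 nt
  ctab <- vapply(split(names(Biostrings::GENETIC_CODE),
                       Biostrings::GENETIC_CODE), min, character(1))
  nt1 <- paste(ctab[strsplit(pep1, "")[[1]]], collapse = "")
  nt2 <- paste(ctab[strsplit(pep2, "")[[1]]], collapse = "")
  intron <- paste0("GTAAGT", strrep("C", 20), "AG")
  sense <- paste0("AAAA", nt1, intron, nt2, "TTTT")
  if (strand == "+") {
    genome <- sense
    e1 <- c(4L, 4L + nchar(nt1))
    e2 <- c(e1[2] + nchar(intron), e1[2] + nchar(intron) + nchar(nt2))
    exons <- tibble::tibble(label = c("1", "2"),
                            start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
  } else {
    N <- nchar(sense)
    genome <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sense)))
    s1 <- c(4L, 4L + nchar(nt1))
    s2 <- c(s1[2] + nchar(intron), s1[2] + nchar(intron) + nchar(nt2))
    exons <- tibble::tibble(label = c("1", "2"),
                            start = c(N - s1[2], N - s2[2]),
                            end = c(N - s1[1], N - s2[1]))
  }
  gene <- gene_model("toy", "chrT", strand, exons, 0L)
  list(gene = gene, genome = tibble::tibble(id = "chrT", seq = genome),
       protein = paste0(pep1, pep2))
}

# shared small training set / model for tests that just need a scorer
shared_pwm <- local({
  tr <- simulate_donor_training_set(n = 300, seed = 424242)
  train_pwm(tr$positives)
})
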