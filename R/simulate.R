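# Seeded synthetic-data generators: donor training sets, a 10-exon
# co-repressor-like locus with planted motifs, donors and (optionally) a
# cryptic GA site, and an orthologue panel with per-species edits. All
# generators are pure functions of (config, seed).

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read a per-position base-frequency model
#'
#' TSV with columns `position`, `A`, `C`, `G`, `T`; every row must sum to
#' 1.
#'
#' @param path File path.
#' @return Numeric matrix (positions by bases).
#' @export
read_freq_model <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, BASES])
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    abort("frequency model rows must sum to 1")
  }
  dimnames(m) <- list(NULL, BASES)
  m
}

#' Default donor-window frequency model
#'
#' Approximates the vertebrate 5' splice-donor consensus
#' `(C/A)AG | GTAAGT` with 70-94% weight on the consensus base per
#' position. The weights live in the package's
#' `extdata/donor_freq_default.tsv`, not in code.
#'
#' @return A 9-by-4 frequency matrix.
#' @export
default_donor_freq_model <- function() {
  read_freq_model(system.file("extdata", "donor_freq_default.tsv",
                              package = "slimsplice"))
}

#' Default SLiM pattern set
#'
#' Loads the package's editable synthetic pattern file: the CoRNR-box
#' consensus and an illustrative SHARP-interaction pattern.
#'
#' @return Named list of [parse_slim_pattern()] objects.
#' @export
default_slim_patterns <- function() {
  read_slim_patterns(system.file("extdata", "motif_patterns_synthetic.tsv",
                                 package = "slimsplice"))
}

# Sample n windows from a per-position frequency model (no seed handling).
sample_freq_windows <- function(freq, n, force_gt = TRUE) {
  L <- nrow(freq)
  if (n == 0) return(character(0))
  cols <- purrr::map(seq_len(L), function(j) {
    sample(BASES, n, replace = TRUE, prob = freq[j, ])
  })
  m <- do.call(cbind, cols)
  if (force_gt && L >= 5) { m[, 4] <- "G"; m[, 5] <- "T" }
  apply(m, 1, paste, collapse = "")
}

# log2(P_model / P_uniform) of windows under a frequency model
freq_model_bits <- function(freq, windows) {
  m <- matrix(match(unlist(strsplit(windows, "")), BASES),
              ncol = nrow(freq), byrow = TRUE)
  lp <- log2(4 * freq)
  rowSums(matrix(lp[cbind(rep(seq_len(ncol(m)), each = nrow(m)),
                          as.vector(m))], nrow = nrow(m)))
}

# One window from the model with no stop codon in any of its three codon
# frames aligned to the cut (used when window bases overwrite coding
# sequence), optionally conditioned on scoring at least `min_bits` against
# a uniform background -- how "a strong donor" is realised; deterministic
# rejection sampling.
sample_donor_window_nostop <- function(freq, min_bits = -Inf) {
  repeat {
    w <- sample_freq_windows(freq, 1)
    codons <- substring(w, c(1, 4, 7), c(3, 6, 9))
    if (any(codons %in% STOP_CODONS)) next
    if (is.finite(min_bits) && freq_model_bits(freq, w) < min_bits) next
    return(w)
  }
}

#' Simulate a donor-window training set with decoys
#'
#' Positives are sampled per position from the frequency model, with
#' window positions 4-5 forced to `GT`; decoys are sampled from an
#' independent background model. Byte-identical across runs with the same
#' seed.
#'
#' @param freq_model Frequency matrix as from [read_freq_model()].
#' @param n Number of positives (and of decoys).
#' @param seed Integer seed.
#' @param background Base-frequency vector for decoys.
#' @return List with donor-window tibbles `positives` and `decoys`.
#' @export
simulate_donor_training_set <- function(freq_model = default_donor_freq_model(),
                                        n, seed,
                                        background = c(0.25, 0.25, 0.25, 0.25)) {
  if (any(abs(rowSums(freq_model) - 1) > 1e-6)) {
    abort("frequency model rows must sum to 1")
  }
  if (n < 0) abort("n must be >= 0")
  with_seed(seed, {
    pos <- sample_freq_windows(freq_model, n, force_gt = TRUE)
    bg <- matrix(rep(background, nrow(freq_model)), nrow = nrow(freq_model),
                 byrow = TRUE)
    dec <- sample_freq_windows(bg, n, force_gt = FALSE)
    list(positives = as_donor_windows(pos), decoys = as_donor_windows(dec))
  })
}

# first codon (alphabetically) per amino acid, from the standard code
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  vapply(split(names(gc), gc), min, character(1))
}

back_translate <- function(peptide, ctab = codon_table()) {
  aa <- chars(peptide)
  bad <- setdiff(aa, names(ctab))
  if (length(bad) > 0) abort(sprintf("cannot back-translate residue '%s'", bad[1]))
  paste(ctab[aa], collapse = "")
}

#' Locus configuration
#'
#' Loads the default configuration (shipped as
#' `extdata/locus_default.yaml`) and applies overrides. Two presets adjust
#' it: `variant = "ncor1"` replaces the internal donor GT with a GA --
#' recording it as the planted cryptic site -- and drops the
#' internal-donor splicing event, mimicking the paralogue that lost
#' alternative splicing by point mutation; `acorn_worm = TRUE` plants the
#' third CoRNR box with its terminal residue mutated, so it is recovered
#' as a partial motif.
#'
#' @param variant `"ncor2"` (default) or `"ncor1"`.
#' @param acorn_worm Plant CoRNR3 with a terminal-residue mismatch?
#' @param path Optional path to a YAML config to load instead of the
#'   default.
#' @param ... Named overrides of top-level config entries.
#' @return A config list for [simulate_locus()].
#' @export
locus_config <- function(variant = c("ncor2", "ncor1"), acorn_worm = FALSE,
                         path = NULL, ...) {
  variant <- match.arg(variant)
  path <- path %||% system.file("extdata", "locus_default.yaml",
                                package = "slimsplice")
  cfg <- yaml::read_yaml(path)
  cfg <- modifyList(cfg, list(...))
  if (variant == "ncor1") {
    cfg$gene_id <- "NCoR1syn"
    cfg$internal_donor$gt <- FALSE
    cfg$events <- purrr::keep(cfg$events, ~ .x$kind != "alternative_internal_donor")
  }
  if (acorn_worm) {
    for (i in seq_along(cfg$motif_placements)) {
      mp <- cfg$motif_placements[[i]]
      if (identical(mp$instance, "CoRNR3")) {
        pep <- mp$peptide
        substr(pep, nchar(pep), nchar(pep)) <- "K"
        cfg$motif_placements[[i]]$peptide <- pep
        cfg$motif_placements[[i]]$status <- "partial"
      }
    }
  }
  cfg$exon_labels <- as.character(cfg$exon_labels)
  cfg
}

events_from_config <- function(cfg) {
  if (length(cfg$events) == 0) {
    return(tibble(event_id = character(0), kind = character(0),
                  exon_label = character(0), cut_index = integer(0)))
  }
  bind_rows(purrr::map(cfg$events, function(e) {
    splice_event(e$event_id, e$kind, as.character(e$exon_label),
                 e$cut_index %||% NA_integer_)
  }))
}

#' Simulate a synthetic multi-exon locus with planted ground truth
#'
#' Builds a genome region containing one gene: back-translated random
#' coding exons joined by canonical `GT..AG` introns, terminal and
#' (optionally) internal splice donors drawn from the configured donor
#' frequency model, planted protein motifs back-translated into the CDS,
#' and -- when the internal donor is configured as GA -- a planted cryptic
#' site one substitution away from a strong donor. Every planted feature
#' is recorded in the returned truth object and is verifiable against the
#' emitted sequences.
#'
#' @param config A [locus_config()] list.
#' @param seed Integer seed.
#' @return A `synthetic_locus` list: `genome` (id/seq tibble), `gene`
#'   ([gene_model()]), `donors` (validated-donor tibble), `events`,
#'   `truth` (planted motifs, donors, cryptic site, events, seed),
#'   `region` (sense-strand gene region sequence), `exon_offsets`
#'   (sense offsets of exons within `region`) and `config`.
#' @export
simulate_locus <- function(config = locus_config(), seed) {
  cfg <- config
  labels <- cfg$exon_labels
  lens <- as.integer(cfg$exon_lengths)
  if (length(lens) != length(labels)) abort("exon_labels/exon_lengths mismatch")
  if (any(lens %% 3 != 0)) {
    abort("synthetic exon lengths must be multiples of 3")
  }
  n_ex <- length(lens)
  intron_lens <- rep(as.integer(cfg$intron_length), length.out = n_ex - 1)
  if (any(intron_lens < 8)) abort("introns must be at least 8 bases")
  freq <- if (identical(cfg$donor_model, "default")) default_donor_freq_model()
          else read_freq_model(cfg$donor_model)
  ctab <- codon_table()

  with_seed(seed, {
    # 1. random coding exons (no stops, by construction)
    exon_seqs <- purrr::map_chr(lens, function(L) {
      back_translate(paste(sample(AA20, L / 3, replace = TRUE), collapse = ""),
                     ctab)
    })
    # 2. plant motifs
    for (mp in cfg$motif_placements) {
      i <- match(as.character(mp$exon), labels)
      if (is.na(i)) abort(sprintf("motif exon '%s' not in exon_labels", mp$exon))
      nt <- back_translate(mp$peptide, ctab)
      off <- as.integer(mp$nt_offset)
      if (off %% 3 != 0) abort("motif nt_offset must be codon-aligned")
      if (off + nchar(nt) > lens[i]) {
        abort(sprintf("motif '%s' does not fit in exon '%s'", mp$instance, mp$exon))
      }
      # donor windows overwrite sequence: refuse colliding placements
      donor_zone <- if (i < n_ex) c(lens[i] - 3L, lens[i]) else NULL
      if (!is.null(cfg$internal_donor) &&
          identical(as.character(cfg$internal_donor$exon), labels[i])) {
        dcut <- as.integer(cfg$internal_donor$cut)
        if (off < dcut + 6L && off + nchar(nt) > dcut - 3L) {
          abort(sprintf("motif '%s' collides with the internal donor window",
                        mp$instance))
        }
      }
      if (!is.null(donor_zone) && off + nchar(nt) > donor_zone[1]) {
        abort(sprintf("motif '%s' collides with the exon-terminal donor window",
                      mp$instance))
      }
      s <- exon_seqs[i]
      substr(s, off + 1L, off + nchar(nt)) <- nt
      exon_seqs[i] <- s
    }
    # 3. terminal stop codon
    if (isTRUE(cfg$terminal_stop)) {
      s <- exon_seqs[n_ex]
      substr(s, lens[n_ex] - 2L, lens[n_ex]) <- "TAA"
      exon_seqs[n_ex] <- s
    }
    # 4. terminal donors for exons 1..n-1: window bases overwrite the last
    # exon codon and seed the first six intron bases
    donor_rows <- list()
    intron_starts <- character(n_ex - 1)
    for (i in seq_len(n_ex - 1)) {
      w <- sample_donor_window_nostop(freq)
      s <- exon_seqs[i]
      substr(s, lens[i] - 2L, lens[i]) <- substr(w, 1, 3)
      exon_seqs[i] <- s
      intron_starts[i] <- substr(w, 4, 9)
      donor_rows[[length(donor_rows) + 1]] <- tibble(
        gene_id = cfg$gene_id, exon_label = labels[i],
        cut_index = lens[i], window = w
      )
    }
    # 5. internal donor / cryptic site in the configured exon
    cryptic <- NULL
    internal_cut <- NA_integer_
    if (!is.null(cfg$internal_donor)) {
      i <- match(as.character(cfg$internal_donor$exon), labels)
      cut <- as.integer(cfg$internal_donor$cut)
      if (is.na(i) || cut %% 3 != 0 || cut + 6 > lens[i] || cut < 3) {
        abort("internal_donor config invalid")
      }
      w <- sample_donor_window_nostop(freq,
                                      min_bits = cfg$internal_donor$min_bits %||% 12)
      s <- exon_seqs[i]
      substr(s, cut - 2L, cut) <- substr(w, 1, 3)
      substr(s, cut + 1L, cut + 6L) <- substr(w, 4, 9)
      if (isTRUE(cfg$internal_donor$gt)) {
        exon_seqs[i] <- s
        internal_cut <- cut
        donor_rows[[length(donor_rows) + 1]] <- tibble(
          gene_id = cfg$gene_id, exon_label = labels[i],
          cut_index = cut, window = w
        )
      } else {
        substr(s, cut + 2L, cut + 2L) <- "A"  # GT -> GA
        exon_seqs[i] <- s
        cryptic <- list(exon_label = labels[i], position = cut,
                        strong_window = w)
      }
    }
    # 6. introns: donor hexamer + random interior + AG acceptor
    introns <- purrr::map_chr(seq_len(n_ex - 1), function(i) {
      mid <- paste(sample(BASES, intron_lens[i] - 8, replace = TRUE),
                   collapse = "")
      paste0(intron_starts[i], mid, "AG")
    })
    flank <- as.integer(cfg$flank)
    flankL <- paste(sample(BASES, flank, replace = TRUE), collapse = "")
    flankR <- paste(sample(BASES, flank, replace = TRUE), collapse = "")

    pieces <- character(0)
    exon_offsets <- integer(n_ex)
    off <- 0L
    for (i in seq_len(n_ex)) {
      exon_offsets[i] <- off
      pieces <- c(pieces, exon_seqs[i])
      off <- off + lens[i]
      if (i < n_ex) {
        pieces <- c(pieces, introns[i])
        off <- off + intron_lens[i]
      }
    }
    region <- paste(pieces, collapse = "")
    assembled <- paste0(flankL, region, flankR)

    strand <- cfg$strand %||% "+"
    N <- nchar(assembled)
    if (strand == "+") {
      genome_seq <- assembled
      starts <- flank + exon_offsets
      ends <- starts + lens
    } else {
      genome_seq <- revcomp(assembled)
      sense_starts <- flank + exon_offsets
      ends <- N - sense_starts
      starts <- ends - lens
    }
    exons <- tibble(label = labels, start = starts, end = ends)
    exons$internal_donors <- purrr::map(seq_len(n_ex), function(i) {
      if (!is.na(internal_cut) &&
          labels[i] == as.character(cfg$internal_donor$exon)) {
        internal_cut
      } else integer(0)
    })
    gene <- gene_model(cfg$gene_id, cfg$contig, strand, exons,
                       cfg$cds_start_phase %||% 0L)
    events <- events_from_config(cfg)
    donors <- as_donor_windows(bind_rows(donor_rows))

    cum_before <- c(0L, cumsum(lens))[seq_len(n_ex)]
    planted_motifs <- bind_rows(purrr::map(cfg$motif_placements, function(mp) {
      i <- match(as.character(mp$exon), labels)
      tibble(pattern_name = mp$pattern, instance = mp$instance,
             exon_label = as.character(mp$exon),
             nt_offset = as.integer(mp$nt_offset),
             protein_start = (cum_before[i] + as.integer(mp$nt_offset)) %/% 3L,
             status = mp$status)
    }))
    truth <- list(
      planted_motifs = planted_motifs,
      planted_donors = select(donors, -"valid"),
      planted_cryptic_site = cryptic,
      events = events,
      seed = as.integer(seed)
    )
    structure(
      list(genome = tibble(id = cfg$contig, seq = genome_seq),
           gene = gene, donors = donors, events = events, truth = truth,
           region = region,
           exon_offsets = stats::setNames(exon_offsets, labels),
           intron_seqs = introns, config = cfg),
      class = "synthetic_locus"
    )
  })
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf("<synthetic_locus> %s: %d exons on %s (%s), %d events, seed %d\n",
              x$gene$gene_id, nrow(x$gene$exons), x$gene$contig,
              x$gene$strand, nrow(x$events), x$truth$seed))
  invisible(x)
}

#' Write a simulated locus to disk
#'
#' Emits `genome.fa`, `gene.gff3`, `donors.tsv`, `events.tsv` and
#' `truth.json` under `dir`.
#'
#' @param locus A [simulate_locus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sequences(locus$genome, file.path(dir, "genome.fa"))
  write_gene_models(locus$gene, file.path(dir, "gene.gff3"))
  write_donor_windows(locus$donors, file.path(dir, "donors.tsv"))
  write_splice_events(locus$events, file.path(dir, "events.tsv"))
  truth <- locus$truth
  truth$planted_motifs <- as.data.frame(truth$planted_motifs)
  truth$planted_donors <- as.data.frame(truth$planted_donors)
  truth$events <- as.data.frame(truth$events)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

# anti-consensus base per window position (lowest-frequency base)
anti_consensus <- function(freq) {
  BASES[apply(freq, 1, which.min)]
}

#' Simulate an orthologue panel of donor-site windows
#'
#' Derives one sequence window per species from a reference locus, centred
#' on the internal donor (or cryptic) site of the configured exon, and
#' applies a per-species edit: `retain` keeps the site and its donor
#' window; `weaken` keeps the GT but rewrites the surrounding seven window
#' bases with anti-consensus bases (a GT in a poor donor context);
#' `lose_gt_to_GA` substitutes the GT's T with A; `delete_region` removes
#' twelve bases around the site. Away from the donor window every species
#' accumulates random substitutions at `divergence` rate, plus optional
#' short indels.
#'
#' @param locus A [simulate_locus()] result whose config declares an
#'   `internal_donor`.
#' @param species_specs Named character vector: species name to one of
#'   `retain`, `weaken`, `lose_gt_to_GA`, `delete_region`.
#' @param seed Integer seed.
#' @param window_size Width of the surveyed window (default 115 bases,
#'   centred on the site).
#' @param divergence Per-base substitution probability outside the donor
#'   window.
#' @param indels Number of random 1-3 base indels per species, placed
#'   downstream of the site (so the site's own coordinate stays
#'   comparable across species before alignment).
#' @return List with `windows` (tibble `species`, `seq`; the reference
#'   species is `ref`), `site_position` (0-based position of the site in
#'   the reference window) and `truth` (tibble `species`, `edit`,
#'   `expected_has_site1`).
#' @export
simulate_ortholog_panel <- function(locus, species_specs, seed,
                                    window_size = 115, divergence = 0.03,
                                    indels = 0) {
  cfg <- locus$config
  if (is.null(cfg$internal_donor)) abort("locus has no internal donor site")
  exon <- as.character(cfg$internal_donor$exon)
  cut <- as.integer(cfg$internal_donor$cut)
  site_region <- locus$exon_offsets[[exon]] + cut  # 0-based, in region coords
  half <- (window_size - 1) %/% 2
  a <- site_region - half
  b <- a + window_size
  if (a < 0 || b > nchar(locus$region)) {
    abort("window extends beyond the simulated region")
  }
  ref <- substr0(locus$region, a, b)
  site <- half  # 0-based position of the site's G within the window
  freq <- if (identical(cfg$donor_model, "default")) default_donor_freq_model()
          else read_freq_model(cfg$donor_model)
  anti <- anti_consensus(freq)
  expected <- c(retain = "yes", weaken = "weak", lose_gt_to_GA = "gt_absent",
                delete_region = "no")
  bad <- setdiff(unname(species_specs), names(expected))
  if (length(bad) > 0) abort(sprintf("unknown species spec '%s'", bad[1]))

  with_seed(seed, {
    rows <- purrr::imap(as.list(species_specs), function(mode, sp) {
      s <- chars(ref)
      win_idx <- (site - 3):(site + 5) + 1L  # 1-based donor window positions
      # background divergence outside the donor window
      mut <- which(runif(length(s)) < divergence)
      mut <- setdiff(mut, win_idx)
      for (i in mut) s[i] <- sample(setdiff(BASES, s[i]), 1)
      if (mode == "weaken") {
        repl <- anti
        repl[4:5] <- c("G", "T")
        s[win_idx] <- repl
      } else if (mode == "lose_gt_to_GA") {
        s[site + 2L] <- "A"
      }
      seq <- paste(s, collapse = "")
      if (mode == "delete_region") {
        del_a <- site - 5L; del_b <- site + 7L  # 0-based, 12 bases
        seq <- paste0(substr0(seq, 0L, del_a),
                      substr0(seq, del_b, nchar(seq)))
      }
      if (indels > 0) {
        for (k in seq_len(indels)) {
          n <- nchar(seq)
          lo <- site + 14L  # downstream of the site so its coordinate is stable
          if (lo >= n - 3L) break
          p <- sample(lo:(n - 3L), 1)
          w <- sample(1:3, 1)
          if (runif(1) < 0.5) {
            seq <- paste0(substr0(seq, 0L, p),
                          paste(sample(BASES, w, replace = TRUE), collapse = ""),
                          substr0(seq, p, n))
          } else {
            seq <- paste0(substr0(seq, 0L, p), substr0(seq, p + w, n))
          }
        }
      }
      tibble(species = sp, seq = seq, edit = mode,
             expected_has_site1 = expected[[mode]])
    })
    panel <- bind_rows(rows)
    windows <- bind_rows(tibble(species = "ref", seq = ref),
                         select(panel, all_of(c("species", "seq"))))
    list(
      windows = windows,
      site_position = site,
      truth = select(panel, all_of(c("species", "edit", "expected_has_site1")))
    )
  })
}
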