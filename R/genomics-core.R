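# Sequence and gene-model core: FASTA/GFF3 I/O, strand-aware splicing and
# translation. Internal coordinates are 0-based half-open throughout; GFF3
# on disk is 1-based inclusive.

#' Read sequences from a FASTA file
#'
#' Sequences are upper-cased on ingest and checked against the declared
#' alphabet. DNA mode accepts `A C G T N`; protein mode accepts the twenty
#' amino acids plus `X` and `*`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @param rna_to_dna If `TRUE`, `U` is normalised to `T` before validation
#'   (DNA mode only).
#' @return A tibble with columns `id` and `seq`, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), f)
#' read_sequences(f)
read_sequences <- function(path, alphabet = c("dna", "protein"),
                           rna_to_dna = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (alphabet == "dna" && rna_to_dna) seqs <- gsub("U", "T", seqs, fixed = TRUE)
  allowed <- if (alphabet == "dna") DNA_ALPHABET else AA_ALPHABET
  for (i in seq_along(seqs)) check_alphabet(seqs[i], allowed, ids[i])
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble with columns `id` and `seq` (as from [read_sequences()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path) {
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model is a strand-aware, ordered set of exons in transcription
#' orientation. Exon coordinates are 0-based half-open on the contig.
#' `internal_donors` holds, per exon, the retained-length cut indices of
#' internal 5' splice donors on the sense strand: a cut `c` means splicing
#' at that donor retains the first `c` sense-strand bases of the exon.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig (sequence) name the exons live on.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble with columns `label`, `start`, `end` and optionally a
#'   list-column `internal_donors` of integer vectors. Exons must be listed
#'   in transcription order (decreasing coordinates on the minus strand).
#' @param cds_start_phase Integer 0-2: number of bases at the 5' end of the
#'   modelled region that complete a codon begun upstream; translation of
#'   the spliced CDS starts after them.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds_start_phase = 0L) {
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (!cds_start_phase %in% 0:2) abort("cds_start_phase must be 0, 1 or 2")
  exons <- as_tibble(exons)
  if (!all(c("label", "start", "end") %in% names(exons))) {
    abort("exons need columns label, start, end")
  }
  if (!"internal_donors" %in% names(exons)) {
    exons$internal_donors <- rep(list(integer(0)), nrow(exons))
  }
  exons$label <- as.character(exons$label)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end)) abort("every exon needs start < end")
  if (anyDuplicated(exons$label)) abort("exon labels must be unique")
  o <- order(exons$start)
  ov <- exons[o, ]
  if (nrow(ov) > 1 && any(ov$start[-1] < ov$end[-nrow(ov)])) {
    abort("exons overlap")
  }
  expected <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(expected, seq_len(nrow(exons)))) {
    abort("exons must be listed in transcription order for the strand")
  }
  lens <- exons$end - exons$start
  for (i in seq_len(nrow(exons))) {
    d <- as.integer(exons$internal_donors[[i]])
    if (length(d) && (any(d <= 0) || any(d >= lens[i]))) {
      abort(sprintf("exon '%s': internal donor cut out of range", exons$label[i]))
    }
    exons$internal_donors[[i]] <- d
  }
  structure(
    list(gene_id = gene_id, contig = contig, strand = strand,
         exons = exons, cds_start_phase = as.integer(cds_start_phase)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s (%s), %d exons, phase %d\n",
              x$gene_id, x$contig, x$strand, nrow(x$exons), x$cds_start_phase))
  print(x$exons, ...)
  invisible(x)
}

# Resolve a genome argument (string, named character or id/seq tibble) to the
# contig sequence a gene model refers to.
contig_seq <- function(genome, contig) {
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome))) {
    return(genome)
  }
  if (is.data.frame(genome)) {
    hit <- genome$seq[genome$id == contig]
    if (length(hit) != 1) abort(sprintf("contig '%s' not found in genome", contig))
    return(hit)
  }
  if (is.character(genome)) {
    if (!contig %in% names(genome)) {
      abort(sprintf("contig '%s' not found in genome", contig))
    }
    return(genome[[contig]])
  }
  abort("genome must be a string, named character vector or id/seq tibble")
}

#' Sense-strand exon sequences of a gene model
#'
#' @param gene A [gene_model()].
#' @param genome Genome sequence: a single string, a named character vector,
#'   or a tibble with `id`/`seq` columns containing the gene's contig.
#' @return Tibble with columns `label` and `seq`, in transcription order.
#' @export
exon_sequences <- function(gene, genome) {
  g <- contig_seq(genome, gene$contig)
  seqs <- substr0(g, gene$exons$start, gene$exons$end)
  if (gene$strand == "-") seqs <- revcomp(seqs)
  tibble(label = gene$exons$label, seq = seqs)
}

# Normalise a choice value to "full" (long / included) or "cut"
# (short / excluded).
normalise_choice <- function(value, event_id) {
  if (isTRUE(value) || value %in% c("long", "included", "full")) return("full")
  if (isFALSE(value) || value %in% c("short", "excluded")) return("cut")
  abort(sprintf("event '%s': unknown selection '%s'", event_id, value))
}

# Retained sense-strand segments per exon after applying splicing choices.
# Returns a tibble: label, sense_start, sense_end (within-exon, sense
# coordinates), genomic_start, genomic_end, cds_start, cds_end (cumulative
# offsets within the spliced CDS).
retained_segments <- function(gene, events = NULL, choices = NULL) {
  ex <- gene$exons
  keep <- rep(TRUE, nrow(ex))
  cut_at <- rep(NA_integer_, nrow(ex))
  if (!is.null(choices) && length(choices) > 0) {
    if (is.null(events)) abort("choices supplied without events")
    if (is.null(names(choices)) || any(names(choices) == "")) {
      abort("choices must be named by event_id")
    }
    unknown <- setdiff(names(choices), events$event_id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown event key: %s", paste(unknown, collapse = ", ")))
    }
    for (eid in names(choices)) {
      sel <- normalise_choice(choices[[eid]], eid)
      if (sel == "full") next
      ev <- events[events$event_id == eid, ]
      i <- match(ev$exon_label, ex$label)
      if (is.na(i)) abort(sprintf("event '%s': exon '%s' not in gene", eid, ev$exon_label))
      if (ev$kind == "cassette_exon") {
        keep[i] <- FALSE
      } else if (ev$kind == "alternative_internal_donor") {
        if (!is.na(cut_at[i])) {
          abort(sprintf("exon '%s': two internal-donor selections", ev$exon_label))
        }
        cut_at[i] <- as.integer(ev$cut_index)
      } else {
        abort(sprintf("event '%s': unknown kind '%s'", eid, ev$kind))
      }
    }
  }
  lens <- ex$end - ex$start
  rows <- list()
  cds_off <- 0L
  for (i in seq_len(nrow(ex))) {
    if (!keep[i]) next
    seg_len <- if (is.na(cut_at[i])) lens[i] else cut_at[i]
    if (seg_len <= 0 || seg_len > lens[i]) {
      abort(sprintf("exon '%s': cut index %d out of range", ex$label[i], cut_at[i]))
    }
    if (gene$strand == "+") {
      gs <- ex$start[i]
      ge <- ex$start[i] + seg_len
    } else {
      gs <- ex$end[i] - seg_len
      ge <- ex$end[i]
    }
    rows[[length(rows) + 1]] <- tibble(
      label = ex$label[i], sense_start = 0L, sense_end = as.integer(seg_len),
      genomic_start = as.integer(gs), genomic_end = as.integer(ge),
      cds_start = cds_off, cds_end = cds_off + as.integer(seg_len)
    )
    cds_off <- cds_off + as.integer(seg_len)
  }
  bind_rows(rows)
}

#' Spliced CDS of a gene model under a set of splicing choices
#'
#' Concatenates the retained sense-strand exon segments in transcription
#' order. An `alternative_internal_donor` event chosen `"short"` retains the
#' first `cut_index` bases of its exon; a `cassette_exon` event chosen
#' `"excluded"` drops the exon. Minus-strand genes are reverse-complemented
#' to the sense strand before concatenation.
#'
#' @inheritParams exon_sequences
#' @param events Tibble of splicing events (see [splice_event()]), or `NULL`.
#' @param choices Named vector/list: `event_id` to `"long"`/`"included"` or
#'   `"short"`/`"excluded"` (logical `TRUE`/`FALSE` also accepted, `TRUE`
#'   meaning long/included). Events not named keep the full exon.
#' @return A single nucleotide string.
#' @export
spliced_cds <- function(gene, genome, events = NULL, choices = NULL) {
  segs <- retained_segments(gene, events, choices)
  if (nrow(segs) == 0) return("")
  g <- contig_seq(genome, gene$contig)
  pieces <- substr0(g, segs$genomic_start, segs$genomic_end)
  if (gene$strand == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation halts at (and excludes) the first stop codon. The returned
#' `stopped` flag reports whether a stop was seen.
#'
#' @param cds Nucleotide string, length at least 3.
#' @param allow_partial If `TRUE`, a trailing partial codon is dropped
#'   silently; otherwise a length not divisible by 3 is an error.
#' @return A list with elements `protein` (amino-acid string) and `stopped`
#'   (logical).
#' @export
#' @examples
#' translate_cds("ATGAAATAA")
translate_cds <- function(cds, allow_partial = FALSE) {
  stopifnot_scalar_string(cds, "cds")
  n <- nchar(cds)
  if (n < 3) abort("cds must be at least 3 bases")
  if (n %% 3 != 0 && !allow_partial) {
    abort(sprintf("cds length %d is not a multiple of 3 (set allow_partial)", n))
  }
  n_codons <- n %/% 3
  starts <- (seq_len(n_codons) - 1L) * 3L + 1L
  codons <- substring(cds, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) {
    list(protein = paste(aa[seq_len(stop_at[1] - 1L)], collapse = ""),
         stopped = TRUE)
  } else {
    list(protein = paste(aa, collapse = ""), stopped = FALSE)
  }
}

#' Protein product of a gene model under splicing choices
#'
#' Convenience wrapper: splices the CDS, drops the leading
#' `cds_start_phase` bases, and translates (tolerating a trailing partial
#' codon, as frame-shifted choices can produce one).
#'
#' @inheritParams spliced_cds
#' @return A list with `cds`, `protein` and `stopped`.
#' @export
gene_protein <- function(gene, genome, events = NULL, choices = NULL) {
  cds <- spliced_cds(gene, genome, events, choices)
  body <- substr0(cds, gene$cds_start_phase, nchar(cds))
  tr <- translate_cds(body, allow_partial = TRUE)
  list(cds = cds, protein = tr$protein, stopped = tr$stopped)
}
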