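# SLiM pattern parsing, protein scanning, exon mapping and the
# species-by-motif acquisition summary.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a degenerate SLiM pattern
#'
#' Patterns are dot-separated position tokens: `x` is a wildcard, and a
#' token like `L/I` allows either residue. The CoRNR box consensus, for
#' example, is `L/I.x.x.I/H.I.x.x.x.I/L`.
#'
#' @param spec Pattern string.
#' @param name Pattern name (e.g. `"CoRNR1"`).
#' @param key_positions Integer vector (1-based position indices) of the
#'   constrained positions whose single mismatch still yields a `"partial"`
#'   call. Defaults to the most C-terminal constrained position, matching
#'   how an otherwise-intact CoRNR box missing only its terminal
#'   leucine/isoleucine is described as incomplete.
#' @return An object of class `slim_pattern`.
#' @export
#' @examples
#' parse_slim_pattern("L/I.x.x.I/H.I.x.x.x.I/L", "CoRNR")
parse_slim_pattern <- function(spec, name, key_positions = NULL) {
  stopifnot_scalar_string(spec, "spec")
  tokens <- strsplit(spec, ".", fixed = TRUE)[[1]]
  if (length(tokens) == 0) abort("empty pattern")
  positions <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok == "") abort(sprintf("empty token at position %d", i))
    if (tok == "x" || tok == "X") {
      positions[i] <- list(NULL)  # wildcard
      next
    }
    aas <- strsplit(tok, "/", fixed = TRUE)[[1]]
    if (any(aas == "") || length(aas) == 0) {
      abort(sprintf("malformed token '%s' at position %d", tok, i))
    }
    aas <- toupper(aas)
    bad <- setdiff(aas, AA20)
    if (length(bad) > 0) {
      abort(sprintf("non-amino-acid letter '%s' at position %d", bad[1], i))
    }
    positions[[i]] <- aas
  }
  constrained <- which(!purrr::map_lgl(positions, is.null))
  if (is.null(key_positions)) {
    key_positions <- if (length(constrained)) max(constrained) else integer(0)
  } else {
    key_positions <- as.integer(key_positions)
    if (!all(key_positions %in% constrained)) {
      abort("key_positions must be constrained positions")
    }
  }
  structure(
    list(name = name, positions = positions, constrained = constrained,
         key_positions = key_positions),
    class = "slim_pattern"
  )
}

#' @export
print.slim_pattern <- function(x, ...) {
  toks <- purrr::map_chr(x$positions, function(p) {
    if (is.null(p)) "x" else paste(p, collapse = "/")
  })
  cat(sprintf("<slim_pattern> %s: %s (key positions: %s)\n",
              x$name, paste(toks, collapse = "."),
              paste(x$key_positions, collapse = ",")))
  invisible(x)
}

#' @export
length.slim_pattern <- function(x) length(x$positions)

#' Read SLiM patterns from a pattern file
#'
#' One pattern per line: `name<TAB>spec<TAB>key_positions` where the third
#' column is an optional comma-separated list of 1-based positions.
#'
#' @param path Path to the pattern TSV (no header). Lines starting with `#`
#'   are ignored.
#' @return A named list of [parse_slim_pattern()] objects.
#' @export
read_slim_patterns <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  pats <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) abort(sprintf("malformed pattern line: '%s'", ln))
    key <- if (length(f) >= 3 && nzchar(f[3])) {
      as.integer(strsplit(f[3], ",", fixed = TRUE)[[1]])
    } else NULL
    pats[[f[1]]] <- parse_slim_pattern(f[2], f[1], key)
  }
  pats
}

#' Scan a protein for a SLiM pattern
#'
#' Every window matching all constrained positions is reported as a
#' `complete` hit. With `allow_partial`, windows matching all constrained
#' positions except exactly one key position are reported as `partial`.
#' Overlapping hits are all reported, sorted by start.
#'
#' @param protein Amino-acid string, or a tibble with `id` and `seq`
#'   columns (every record is scanned).
#' @param pattern A [parse_slim_pattern()] object, or a list of them.
#' @param allow_partial Report single-key-mismatch windows as `partial`?
#' @param protein_id Identifier used when `protein` is a plain string.
#' @return Tibble of hits: `pattern_name`, `protein_id`, `start`, `end`
#'   (0-based half-open peptide coordinates), `status`
#'   (`"complete"`/`"partial"`) and list-column `mismatched_positions`.
#' @export
scan_protein <- function(protein, pattern, allow_partial = TRUE,
                         protein_id = "protein") {
  if (is.data.frame(protein)) {
    out <- purrr::pmap(protein, function(id, seq, ...) {
      scan_protein(seq, pattern, allow_partial, protein_id = id)
    })
    return(bind_rows(out))
  }
  if (inherits(pattern, "slim_pattern")) pattern <- list(pattern)
  bind_rows(purrr::map(pattern, function(p) {
    scan_protein_one(protein, p, allow_partial, protein_id)
  }))
}

scan_protein_one <- function(protein, pattern, allow_partial, protein_id) {
  m <- length(pattern$positions)
  aa <- chars(protein)
  n <- length(aa)
  empty <- tibble(
    pattern_name = character(0), protein_id = character(0),
    start = integer(0), end = integer(0), status = character(0),
    mismatched_positions = list()
  )
  if (n < m) return(empty)
  n_win <- n - m + 1L
  # mismatch indicator per window x constrained position
  mis <- matrix(FALSE, nrow = n_win, ncol = length(pattern$constrained))
  for (k in seq_along(pattern$constrained)) {
    j <- pattern$constrained[k]
    mis[, k] <- !(aa[seq_len(n_win) + j - 1L] %in% pattern$positions[[j]])
  }
  n_mis <- rowSums(mis)
  rows <- list()
  for (w in seq_len(n_win)) {
    if (n_mis[w] == 0) {
      rows[[length(rows) + 1]] <- list(start = w - 1L, status = "complete",
                                       mismatched = integer(0))
    } else if (allow_partial && n_mis[w] == 1) {
      bad <- pattern$constrained[which(mis[w, ])]
      if (bad %in% pattern$key_positions) {
        rows[[length(rows) + 1]] <- list(start = w - 1L, status = "partial",
                                         mismatched = bad)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  tibble(
    pattern_name = pattern$name,
    protein_id = protein_id,
    start = purrr::map_int(rows, "start"),
    end = purrr::map_int(rows, "start") + m,
    status = purrr::map_chr(rows, "status"),
    mismatched_positions = purrr::map(rows, "mismatched")
  ) |> arrange(.data$start)
}

#' Map a motif hit onto its encoding exons
#'
#' Converts peptide coordinates of a hit back to CDS nucleotide coordinates
#' (times three, adjusted for the CDS start phase) and then to genomic
#' sub-intervals via the splicing choices the hit's protein was produced
#' under. A motif spanning a splice junction yields one sub-interval per
#' exon.
#'
#' @param hit One hit: a one-row tibble from [scan_protein()] (or any list
#'   with `start` and `end` peptide coordinates).
#' @inheritParams spliced_cds
#' @return Tibble with one row per overlapped exon, in transcription order:
#'   `exon_label`, `genomic_start`, `genomic_end` (0-based half-open),
#'   `strand`, `cds_start`, `cds_end`.
#' @export
map_hit_to_exons <- function(hit, gene, genome, events = NULL, choices = NULL) {
  if (is.data.frame(hit)) {
    if (nrow(hit) != 1) abort("map_hit_to_exons takes a single hit")
    hit <- as.list(hit)
  }
  segs <- retained_segments(gene, events, choices)
  cds_len <- max(segs$cds_end)
  nt_start <- gene$cds_start_phase + 3L * as.integer(hit$start)
  nt_end <- gene$cds_start_phase + 3L * as.integer(hit$end)
  if (nt_end > cds_len) abort("hit extends beyond the spliced CDS")
  out <- list()
  for (i in seq_len(nrow(segs))) {
    a <- max(nt_start, segs$cds_start[i])
    b <- min(nt_end, segs$cds_end[i])
    if (a >= b) next
    off_a <- a - segs$cds_start[i]
    off_b <- b - segs$cds_start[i]
    if (gene$strand == "+") {
      gs <- segs$genomic_start[i] + off_a
      ge <- segs$genomic_start[i] + off_b
    } else {
      gs <- segs$genomic_end[i] - off_b
      ge <- segs$genomic_end[i] - off_a
    }
    out[[length(out) + 1]] <- tibble(
      exon_label = segs$label[i],
      genomic_start = as.integer(gs), genomic_end = as.integer(ge),
      strand = gene$strand, cds_start = a, cds_end = b
    )
  }
  bind_rows(out)
}

#' Species-by-motif acquisition matrix
#'
#' Summarises motif presence across a species panel: a cell is `complete`
#' if the species has at least one complete hit for the motif, else
#' `partial` if it has a partial hit, else `absent`.
#'
#' @param hits Tibble of hits with a `species` column plus the columns of
#'   [scan_protein()] output (at least `pattern_name` and `status`).
#' @param motif_names Ordered character vector of motif (pattern) names to
#'   report as columns.
#' @param species Optional ordered character vector of species to report as
#'   rows (defaults to those present in `hits`).
#' @return A wide tibble: one row per species, one column per motif, values
#'   in `absent`/`partial`/`complete`.
#' @export
motif_acquisition_matrix <- function(hits, motif_names, species = NULL) {
  if (is.null(species)) species <- unique(hits$species)
  grid <- tidyr::expand_grid(species = species, pattern_name = motif_names)
  lev <- c("absent", "partial", "complete")
  calls <- hits |>
    filter(.data$pattern_name %in% motif_names, .data$species %in% !!species) |>
    group_by(.data$species, .data$pattern_name) |>
    summarise(call = {
      r <- match(.data$status, lev)
      lev[if (length(r)) max(r) else 1L]
    }, .groups = "drop")
  grid |>
    left_join(calls, by = c("species", "pattern_name")) |>
    mutate(call = dplyr::coalesce(.data$call, "absent")) |>
    tidyr::pivot_wider(names_from = "pattern_name", values_from = "call") |>
    select(all_of(c("species", motif_names)))
}

#' Validate NCoR-family membership of a candidate protein
#'
#' A candidate is accepted when it has at least two complete CoRNR-box
#' hits, a SHARP-interaction hit that lies after all CoRNR hits and is the
#' most C-terminal motif hit of all, and at least two SANT domains (the
#' SANT count comes from external annotation and is supplied as a number).
#'
#' @param hits Tibble of hits from [scan_protein()], for one protein.
#' @param sant_count Number of annotated SANT domains upstream.
#' @param cornr_names,sharp_names Pattern names counted as CoRNR boxes and
#'   as the SHARP motif; defaults match names starting `CoRNR` / `SHARP`.
#' @return A list with `accept` (logical) and `reasons` (character vector
#'   of failed clauses: `"CoRNR"`, `"SHARP"`, `"order"`, `"SANT"`).
#' @export
validate_family_membership <- function(hits, sant_count,
                                       cornr_names = NULL, sharp_names = NULL) {
  is_cornr <- if (is.null(cornr_names)) grepl("^CoRNR", hits$pattern_name)
              else hits$pattern_name %in% cornr_names
  is_sharp <- if (is.null(sharp_names)) grepl("^SHARP", hits$pattern_name)
              else hits$pattern_name %in% sharp_names
  reasons <- character(0)
  cornr <- hits[is_cornr & hits$status == "complete", ]
  sharp <- hits[is_sharp, ]
  if (nrow(cornr) < 2) reasons <- c(reasons, "CoRNR")
  if (nrow(sharp) < 1) {
    reasons <- c(reasons, "SHARP")
  } else {
    best_sharp <- max(sharp$start)
    after_cornr <- nrow(cornr) == 0 || best_sharp > max(cornr$start)
    most_cterm <- best_sharp >= max(hits$start)
    if (!(after_cornr && most_cterm)) reasons <- c(reasons, "order")
  }
  if (sant_count < 2) reasons <- c(reasons, "SANT")
  list(accept = length(reasons) == 0, reasons = reasons)
}

#' Write motif hits as TSV or BED
#'
#' The BED projection requires genomic mapping columns as produced by
#' [map_hit_to_exons()] (`genomic_start`, `genomic_end`, plus a `contig`
#' column); it is written 0-based half-open.
#'
#' @param hits Hits tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- hits
    if ("mismatched_positions" %in% names(out)) {
      out$mismatched_positions <- purrr::map_chr(
        out$mismatched_positions, paste, collapse = ","
      )
    }
    readr::write_tsv(out, path)
  } else {
    need <- c("contig", "genomic_start", "genomic_end")
    if (!all(need %in% names(hits))) {
      abort("BED output needs columns contig, genomic_start, genomic_end")
    }
    bed <- tibble(
      chrom = hits$contig,
      chromStart = hits$genomic_start,
      chromEnd = hits$genomic_end,
      name = paste(hits$pattern_name, hits$status, sep = "|"),
      score = 0L,
      strand = hits$strand %||% "+"
    )
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}
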