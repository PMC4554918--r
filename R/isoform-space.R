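# Isoform enumeration over binary alternative-splicing events and the
# motif complement of each isoform.

#' Construct splicing events
#'
#' A binary alternative-splicing event: a `cassette_exon` is included or
#' excluded whole; an `alternative_internal_donor` chooses between the
#' exon-terminal donor (long) and an internal donor at `cut_index`
#' (short).
#'
#' @param event_id Unique event identifier.
#' @param kind `"cassette_exon"` or `"alternative_internal_donor"`.
#' @param exon_label Label of the exon the event acts on.
#' @param cut_index Retained-length cut for internal-donor events.
#' @return A one-row events tibble; rows can be combined with
#'   [dplyr::bind_rows()].
#' @export
splice_event <- function(event_id, kind, exon_label, cut_index = NA_integer_) {
  kind <- match.arg(kind, c("cassette_exon", "alternative_internal_donor"))
  if (kind == "alternative_internal_donor" && is.na(cut_index)) {
    abort("alternative_internal_donor events need a cut_index")
  }
  tibble(event_id = as.character(event_id), kind = kind,
         exon_label = as.character(exon_label),
         cut_index = as.integer(cut_index))
}

#' Read / write an events table
#'
#' TSV with columns `event_id`, `kind`, `exon_label`, `cut_index`.
#'
#' @param path File path.
#' @return `read_splice_events()`: an events tibble.
#' @export
read_splice_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ev <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          event_id = "c", kind = "c", exon_label = "c",
                          cut_index = "i"))
  ev
}

#' @rdname read_splice_events
#' @param events Events tibble.
#' @export
write_splice_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

check_events <- function(gene, events) {
  if (anyDuplicated(events$event_id)) abort("duplicate event_id")
  missing <- setdiff(events$exon_label, gene$exons$label)
  if (length(missing) > 0) {
    abort(sprintf("events reference unknown exon(s): %s",
                  paste(missing, collapse = ", ")))
  }
  lens <- stats::setNames(gene$exons$end - gene$exons$start, gene$exons$label)
  don <- events$kind == "alternative_internal_donor"
  bad <- don & (is.na(events$cut_index) | events$cut_index <= 0 |
                  events$cut_index >= lens[events$exon_label])
  if (any(bad)) {
    abort(sprintf("invalid cut_index for event(s): %s",
                  paste(events$event_id[bad], collapse = ", ")))
  }
  invisible(events)
}

#' Enumerate all transcript isoforms over binary splicing events
#'
#' Produces exactly `2^k` isoforms for `k` events, one per choice vector,
#' in deterministic order (binary counting over events in input order,
#' long/included first). Isoform identity is the choice vector, not the
#' protein: distinct choices yielding identical proteins remain distinct
#' isoforms. Choices that break the reading frame are permitted but
#' flagged, and their proteins are translated to the first stop.
#'
#' @inheritParams spliced_cds
#' @param events Events tibble ([splice_event()] rows); may be empty.
#' @return Tibble with one row per isoform: `isoform_id`, list-column
#'   `choices` (named character vector), `cds`, `protein`, `stopped`,
#'   `frameshift`.
#' @export
enumerate_isoforms <- function(gene, genome, events = NULL) {
  if (is.null(events)) {
    events <- tibble(event_id = character(0), kind = character(0),
                     exon_label = character(0), cut_index = integer(0))
  }
  check_events(gene, events)
  k <- nrow(events)
  full_len <- nchar(spliced_cds(gene, genome)) - gene$cds_start_phase
  rows <- purrr::map(seq_len(2^k) - 1L, function(code) {
    bits <- if (k > 0) (code %/% 2^(seq_len(k) - 1L)) %% 2L else integer(0)
    choices <- stats::setNames(
      ifelse(bits == 0,
             ifelse(events$kind == "cassette_exon", "included", "long"),
             ifelse(events$kind == "cassette_exon", "excluded", "short")),
      events$event_id
    )
    res <- gene_protein(gene, genome, events, as.list(choices))
    body_len <- nchar(res$cds) - gene$cds_start_phase
    tibble(
      isoform_id = if (k > 0) paste0("iso_", paste(bits, collapse = "")) else "iso_full",
      choices = list(choices),
      cds = res$cds, protein = res$protein, stopped = res$stopped,
      frameshift = (full_len - body_len) %% 3 != 0
    )
  })
  bind_rows(rows)
}

#' Motif complement of isoforms
#'
#' Scans each isoform's protein for every pattern and reports the combined
#' hit table; the motif complement of an isoform is its multiset of
#' (pattern, status) hits.
#'
#' @param isoforms Output of [enumerate_isoforms()] (or any tibble with
#'   `isoform_id` and `protein`).
#' @param patterns A [parse_slim_pattern()] object or list of them.
#' @param allow_partial Passed to [scan_protein()].
#' @return Tibble of hits with an `isoform_id` column (named `protein_id`
#'   in [scan_protein()] output is replaced by the isoform id).
#' @export
isoform_motif_complement <- function(isoforms, patterns, allow_partial = TRUE) {
  out <- purrr::map2(isoforms$isoform_id, isoforms$protein, function(id, prot) {
    hits <- scan_protein(prot, patterns, allow_partial, protein_id = id)
    names(hits)[names(hits) == "protein_id"] <- "isoform_id"
    hits
  })
  bind_rows(out)
}

#' Summarise isoform motif complements
#'
#' @param complements Output of [isoform_motif_complement()].
#' @param isoforms The isoforms tibble (to include hit-free isoforms).
#' @return Tibble: `isoform_id`, `pattern_name`, `status`, `n_hits`.
#' @export
motif_complement_summary <- function(complements, isoforms = NULL) {
  out <- complements |>
    group_by(.data$isoform_id, .data$pattern_name, .data$status) |>
    summarise(n_hits = dplyr::n(), .groups = "drop")
  if (!is.null(isoforms)) {
    missing <- setdiff(isoforms$isoform_id, out$isoform_id)
    if (length(missing) > 0) {
      out <- bind_rows(out, tibble(isoform_id = missing,
                                   pattern_name = NA_character_,
                                   status = NA_character_, n_hits = 0L))
    }
  }
  arrange(out, .data$isoform_id, .data$pattern_name)
}
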