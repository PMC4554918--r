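# GFF3 reading/writing of gene models through rtracklayer. On disk the
# convention is standard GFF3 (1-based inclusive); exon features carry a
# `label` attribute and internal donors are `five_prime_cis_splice_site`
# features spanning the first two excised (intron-side) bases. A sidecar
# donors TSV (`gene_id, exon_label, cut_index`) is also accepted.

#' Write gene models to a GFF3 file
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features, with exon `label`
#' attributes and internal donors as 2-base `five_prime_cis_splice_site`
#' features.
#'
#' @param models A [gene_model()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  grs <- purrr::map(models, gene_model_to_granges)
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

gene_model_to_granges <- function(gene) {
  ex <- gene$exons
  n <- nrow(ex)
  lens <- ex$end - ex$start
  gid <- gene$gene_id
  tid <- paste0(gid, ".t1")
  span_start <- min(ex$start) + 1L
  span_end <- max(ex$end)
  # CDS phase per GFF3: bases to skip at feature start to reach a codon
  # boundary, walking exons in transcription order.
  cum_before <- c(0L, cumsum(lens))[seq_len(n)]
  phase <- (3L - ((cum_before - gene$cds_start_phase) %% 3L)) %% 3L

  starts <- integer(0); ends <- integer(0); types <- character(0)
  ids <- character(0); parents <- character(0); labels <- character(0)
  phases <- integer(0)

  add <- function(type, s1, e1, id, parent, label = NA_character_,
                  ph = NA_integer_) {
    starts <<- c(starts, s1); ends <<- c(ends, e1); types <<- c(types, type)
    ids <<- c(ids, id); parents <<- c(parents, parent)
    labels <<- c(labels, label); phases <<- c(phases, ph)
  }

  add("gene", span_start, span_end, gid, NA_character_)
  add("mRNA", span_start, span_end, tid, gid)
  for (i in seq_len(n)) {
    s1 <- ex$start[i] + 1L; e1 <- ex$end[i]
    add("exon", s1, e1, sprintf("%s.exon.%s", gid, ex$label[i]), tid,
        ex$label[i])
    add("CDS", s1, e1, sprintf("%s.cds.%s", gid, ex$label[i]), tid,
        ex$label[i], phase[i])
    for (cut in ex$internal_donors[[i]]) {
      if (gene$strand == "+") {
        ds1 <- ex$start[i] + cut + 1L; de1 <- ex$start[i] + cut + 2L
      } else {
        ds1 <- ex$end[i] - cut - 1L; de1 <- ex$end[i] - cut
      }
      add("five_prime_cis_splice_site", ds1, de1,
          sprintf("%s.donor.%s.%d", gid, ex$label[i], cut), tid, ex$label[i])
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = gene$contig,
    ranges = IRanges::IRanges(starts, ends),
    strand = gene$strand
  )
  S4Vectors::mcols(gr)$type <- types
  S4Vectors::mcols(gr)$ID <- ids
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(parents), "", parents)
  S4Vectors::mcols(gr)$label <- labels
  S4Vectors::mcols(gr)$phase <- phases
  gr
}

#' Read gene models from a GFF3 file
#'
#' Inverse of [write_gene_models()]: converts 1-based inclusive GFF3
#' coordinates to the internal 0-based half-open convention, re-orders
#' minus-strand exons into transcription order, takes `cds_start_phase`
#' from the first CDS feature and collects internal donors from
#' `five_prime_cis_splice_site` features and/or a sidecar donors table.
#'
#' @param path Path to a GFF3 file.
#' @param donors Optional sidecar: a TSV path or tibble with columns
#'   `gene_id`, `exon_label`, `cut_index`.
#' @return A named list of [gene_model()] objects (names are gene ids).
#' @export
read_gene_models <- function(path, donors = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(mc)) {
    purrr::map_chr(as.list(mc$Parent), function(p) if (length(p)) p[[1]] else NA_character_)
  } else rep(NA_character_, length(gr))
  labels <- if ("label" %in% names(mc)) as.character(mc$label) else rep(NA_character_, length(gr))

  # Map every feature to its gene id by walking Parent links upward.
  parent_of <- stats::setNames(parents, ids)
  gene_ids <- ids[type == "gene"]
  to_gene <- function(id) {
    seen <- character(0)
    while (!is.na(id) && !id %in% gene_ids && !id %in% seen) {
      seen <- c(seen, id)
      id <- parent_of[[id]] %||% NA_character_
    }
    id
  }
  feat_gene <- purrr::map_chr(seq_along(gr), function(i) {
    if (type[i] == "gene") return(ids[i])
    anchor <- if (!is.na(parents[i])) parents[i] else ids[i]
    to_gene(anchor)
  })
  if (!any(type == "exon")) abort("GFF3 contains no exon features")

  sidecar <- NULL
  if (!is.null(donors)) {
    sidecar <- if (is.character(donors)) {
      readr::read_tsv(donors, show_col_types = FALSE)
    } else as_tibble(donors)
  }

  models <- list()
  for (gid in unique(stats::na.omit(feat_gene))) {
    sel <- which(feat_gene == gid)
    ex_i <- sel[type[sel] == "exon"]
    if (length(ex_i) == 0) abort(sprintf("gene '%s' has no exon features", gid))
    strand <- as.character(GenomicRanges::strand(gr[ex_i[1]]))
    contig <- as.character(GenomicRanges::seqnames(gr[ex_i[1]]))
    ex <- tibble(
      label = ifelse(is.na(labels[ex_i]), as.character(seq_along(ex_i)), labels[ex_i]),
      start = GenomicRanges::start(gr[ex_i]) - 1L,  # GFF3 1-based -> 0-based
      end = GenomicRanges::end(gr[ex_i])
    )
    ex <- ex[order(if (strand == "+") ex$start else -ex$start), ]
    # phase of the transcription-order first CDS
    cds_i <- sel[type[sel] == "CDS"]
    phase0 <- 0L
    if (length(cds_i) > 0) {
      first <- if (strand == "+") cds_i[which.min(GenomicRanges::start(gr[cds_i]))]
               else cds_i[which.max(GenomicRanges::end(gr[cds_i]))]
      ph <- mc$phase[first]
      if (!is.null(ph) && !is.na(ph)) phase0 <- as.integer(ph)
    }
    # internal donors from splice-site features
    ex$internal_donors <- rep(list(integer(0)), nrow(ex))
    don_i <- sel[type[sel] == "five_prime_cis_splice_site"]
    for (i in don_i) {
      a <- GenomicRanges::start(gr[i]) - 1L; b <- GenomicRanges::end(gr[i])
      j <- which(ex$start <= a & b <= ex$end)
      if (length(j) != 1) next
      cut <- if (strand == "+") a - ex$start[j] else ex$end[j] - b
      ex$internal_donors[[j]] <- sort(unique(c(ex$internal_donors[[j]], as.integer(cut))))
    }
    if (!is.null(sidecar)) {
      extra <- sidecar[sidecar$gene_id == gid, ]
      for (k in seq_len(nrow(extra))) {
        j <- match(extra$exon_label[k], ex$label)
        if (is.na(j)) abort(sprintf("donor table: exon '%s' not in gene '%s'",
                                    extra$exon_label[k], gid))
        cut <- as.integer(extra$cut_index[k])
        if (cut < ex$end[j] - ex$start[j]) {
          ex$internal_donors[[j]] <- sort(unique(c(ex$internal_donors[[j]], cut)))
        }
      }
    }
    models[[gid]] <- gene_model(gid, contig, strand, ex, phase0)
  }
  models
}
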