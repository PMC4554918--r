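# Cryptic-donor scan: enumerate dinucleotides one substitution away from
# GT, score the mutated donor windows, compare against the validated-donor
# distribution and filter by reading-frame compatibility.

# dinucleotides at Hamming distance 1 from GT
GT_DISTANCE1 <- c("GA", "GG", "GC", "AT", "CT", "TT")

#' Enumerate dinucleotides convertible to GT by one substitution
#'
#' Walks every dinucleotide position in the exon and keeps those whose
#' dinucleotide is within Hamming distance 1 of `GT` (distance-0 existing
#' `GT` sites only when `include_existing`). For each candidate the mutated
#' nine-base donor window is built from the exon with the substitution
#' applied; the retained-length cut implied by a candidate at position `p`
#' is `p` (the GT becomes the first excised base pair). Candidates whose
#' window lacks context (within three bases of the exon start, or short of
#' right-side sequence) are flagged, not dropped.
#'
#' @param exon_seq Sense-strand exon sequence (length >= 4).
#' @param downstream_flank Sense-strand sequence following the exon,
#'   supplying right-side window context for candidates near the exon end.
#' @param include_existing Also report existing `GT` dinucleotides
#'   (distance 0, no substitution), so real internal donors can be
#'   surveyed with the same machinery.
#' @param exon_label Carried into the output.
#' @return Tibble with one row per candidate: `exon_label`, `position`
#'   (0-based index of the dinucleotide's first base), `original`,
#'   `sub_offset` (0/1 within the dinucleotide, `NA` for existing GT),
#'   `sub_base`, `window` (mutated; `NA` when context is missing), `valid`,
#'   `flag` (`"insufficient_exonic_context"`, `"insufficient_flank"` or
#'   `NA`).
#' @export
enumerate_gt_candidates <- function(exon_seq, downstream_flank = "",
                                    include_existing = FALSE,
                                    exon_label = NA_character_) {
  exon_seq <- toupper(exon_seq); downstream_flank <- toupper(downstream_flank)
  L <- nchar(exon_seq)
  if (L < 4) abort("exon must be at least 4 bases")
  din <- substring(exon_seq, seq_len(L - 1), seq_len(L - 1) + 1)
  keep <- din %in% GT_DISTANCE1 | (include_existing & din == "GT")
  pos <- which(keep) - 1L  # 0-based
  if (length(pos) == 0) {
    return(tibble(exon_label = character(0), position = integer(0),
                  original = character(0), sub_offset = integer(0),
                  sub_base = character(0), window = character(0),
                  valid = logical(0), flag = character(0)))
  }
  rows <- purrr::map(pos, function(p) {
    d <- substr0(exon_seq, p, p + 2L)
    if (d == "GT") {
      off <- NA_integer_; nb <- NA_character_
      mutated <- exon_seq
    } else {
      off <- if (substr(d, 1, 1) != "G") 0L else 1L
      nb <- if (off == 0L) "G" else "T"
      mutated <- exon_seq
      substr(mutated, p + off + 1L, p + off + 1L) <- nb
    }
    flag <- NA_character_; win <- NA_character_; valid <- FALSE
    if (p < 3) {
      flag <- "insufficient_exonic_context"
    } else {
      right <- paste0(substr0(mutated, p, L), downstream_flank)
      if (nchar(right) < 6) {
        flag <- "insufficient_flank"
      } else {
        win <- paste0(substr0(mutated, p - 3L, p), substr0(right, 0L, 6L))
        valid <- !grepl("[^ACGT]", win)
      }
    }
    tibble(exon_label = exon_label, position = p, original = d,
           sub_offset = off, sub_base = nb, window = win,
           valid = valid, flag = flag)
  })
  bind_rows(rows)
}

#' Is an internal donor reading-frame compatible?
#'
#' An internal donor at retained length `cut` preserves the reading frame
#' into the next exon exactly when the excised length `exon_length - cut`
#' is divisible by 3.
#'
#' @param exon_length Exon length in bases.
#' @param cut Retained-length cut index, `0 < cut <= exon_length`.
#' @return Logical (vectorised over `cut`).
#' @export
frame_compatible <- function(exon_length, cut) {
  if (any(cut <= 0 | cut > exon_length)) {
    abort("cut must satisfy 0 < cut <= exon_length")
  }
  (exon_length - cut) %% 3 == 0
}

#' Score and rank GT-creation candidates
#'
#' Scores each candidate's mutated window under the model, standardises
#' against the validated-donor distribution (`z = (score - mean)/sd`),
#' flags candidates exceeding the validated-donor mean (the reporting
#' criterion for a strong site), and adds reading-frame compatibility of
#' the implied cut. Results are sorted by score descending with ties
#' broken by ascending position; unscorable candidates sort last.
#'
#' @param candidates Output of [enumerate_gt_candidates()].
#' @param model A `splice_model`.
#' @param stats Validated-donor statistics from [donor_score_stats()]
#'   (`n >= 2`).
#' @param exon_length Exon length, for the frame flag; if `NA` the
#'   `frame_compatible` column is `NA`.
#' @return The candidates tibble with `score`, `z`, `exceeds_mean` and
#'   `frame_compatible` columns, sorted.
#' @export
score_candidates <- function(candidates, model, stats, exon_length = NA) {
  if (stats$n < 2) abort("stats must come from at least 2 validated donors")
  out <- candidates
  out$score <- NA_real_
  ok <- which(!is.na(out$window) & out$valid)
  if (length(ok) > 0) {
    out$score[ok] <- score_windows(model, out$window[ok])$score
  }
  out$z <- (out$score - stats$mean) / stats$sd
  out$exceeds_mean <- !is.na(out$score) & out$score > stats$mean
  out$frame_compatible <- NA
  if (!is.na(exon_length)) {
    ok_cut <- out$position > 0 & out$position <= exon_length
    out$frame_compatible[ok_cut] <-
      frame_compatible(exon_length, out$position[ok_cut])
  }
  out |> arrange(dplyr::desc(!is.na(.data$score)), desc(.data$score), .data$position)
}

#' Run the full cryptic-donor scan on one exon
#'
#' Convenience pipeline: enumerate candidates, score them against a model
#' and validated-donor statistics, and attach frame compatibility.
#'
#' @inheritParams enumerate_gt_candidates
#' @inheritParams score_candidates
#' @return A scored, sorted candidates tibble (see [score_candidates()]).
#' @export
mutation_scan <- function(exon_seq, downstream_flank = "", model, stats,
                          include_existing = FALSE,
                          exon_label = NA_character_) {
  cand <- enumerate_gt_candidates(exon_seq, downstream_flank,
                                  include_existing, exon_label)
  score_candidates(cand, model, stats, exon_length = nchar(exon_seq))
}

#' Find the first in-frame stop codon
#'
#' Scans codons beginning at `frame_offset` and returns the 0-based start
#' of the first `TAA`/`TAG`/`TGA` whose start lies within `horizon` bases,
#' or `NA` if none. Used to ask whether skipping a donor would run into a
#' truncating stop shortly downstream.
#'
#' @param seq Nucleotide sequence.
#' @param frame_offset 0, 1 or 2: offset of the first codon start.
#' @param horizon Number of bases (from the sequence start) within which a
#'   stop's first base must fall. Defaults to the whole sequence.
#' @return Integer position or `NA_integer_`.
#' @export
inframe_stop_scan <- function(seq, frame_offset = 0, horizon = nchar(seq)) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (horizon > n) abort("horizon exceeds sequence length")
  if (!frame_offset %in% 0:2) abort("frame_offset must be 0, 1 or 2")
  starts <- seq.int(frame_offset, n - 3, by = 3)
  if (length(starts) == 0) return(NA_integer_)
  codons <- substring(seq, starts + 1, starts + 3)
  hit <- which(codons %in% c("TAA", "TAG", "TGA") & starts < horizon)
  if (length(hit) == 0) NA_integer_ else as.integer(starts[hit[1]])
}
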