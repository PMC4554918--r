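# Cross-species donor-site conservation: survey GT dinucleotides and their
# strengths across an orthologous sequence window, and decide per species
# whether the homologue of a reference donor ("site 1") is present.

#' Survey GT dinucleotides across a sequence window
#'
#' Reports every occurrence of `GT` that has enough context to form a
#' nine-base donor window (three bases to the left, four more to the
#' right), with its score. Overlapping GTs (as in `GTGT`) are each
#' reported.
#'
#' @param window_seq Nucleotide sequence (length >= 9).
#' @param model A `splice_model` for nine-base windows.
#' @return Tibble with columns `position` (0-based index of the `G`),
#'   `window` and `score`.
#' @export
window_gt_survey <- function(window_seq, model) {
  window_seq <- toupper(window_seq)
  n <- nchar(window_seq)
  if (n < 9) abort("window must be at least 9 bases")
  starts <- seq_len(n - 1)
  din <- substring(window_seq, starts, starts + 1)
  pos <- which(din == "GT") - 1L  # 0-based
  pos <- pos[pos >= 3 & pos + 6 <= n]
  if (length(pos) == 0) {
    return(tibble(position = integer(0), window = character(0),
                  score = numeric(0)))
  }
  wins <- substring(window_seq, pos - 2L, pos + 6L)
  tibble(position = pos, window = wins,
         score = score_windows(model, wins)$score)
}

#' Map a reference position onto an orthologous sequence
#'
#' Global (Needleman-Wunsch) pairwise alignment of the two sequences,
#' returning the 0-based position in `other_seq` that aligns with
#' `ref_position` in `ref_seq`, or `NA` if that column is a gap in the
#' other sequence.
#'
#' @param ref_seq,other_seq Nucleotide sequences.
#' @param ref_position 0-based position in `ref_seq`.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (defaults
#'   +1/-1/-4/-1).
#' @return Integer position or `NA_integer_`.
#' @export
map_homologous_site <- function(ref_seq, ref_position, other_seq,
                                match = 1, mismatch = -1,
                                gap_open = -4, gap_extend = -1) {
  if (nchar(ref_seq) == 0 || nchar(other_seq) == 0) {
    abort("sequences must be non-empty")
  }
  if (ref_position < 0 || ref_position >= nchar(ref_seq)) {
    abort("ref_position outside ref_seq")
  }
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    toupper(ref_seq), toupper(other_seq), type = "global",
    substitutionMatrix = sub,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend)
  )
  pa <- chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- chars(as.character(Biostrings::alignedSubject(aln)))
  i <- 0L; j <- 0L
  for (col in seq_along(pa)) {
    ref_gap <- pa[col] == "-"
    oth_gap <- sa[col] == "-"
    if (!oth_gap) j <- j + 1L
    if (!ref_gap) {
      i <- i + 1L
      if (i - 1L == ref_position) {
        return(if (oth_gap) NA_integer_ else j - 1L)
      }
    }
  }
  NA_integer_
}

#' Cross-species conservation of a reference donor site
#'
#' For each species, maps the homologous position of the reference site by
#' pairwise alignment against the reference sequence and classifies it:
#' `yes` when the dinucleotide there is `GT` scoring at least
#' `weak_threshold`; `weak` when it is `GT` below threshold (a site
#' present but part of a poor consensus donor); `gt_absent` when the
#' homologous position exists but carries another dinucleotide (e.g. the
#' `GA` substitution pattern); `no` when the position does not map.
#'
#' @param windows Tibble with columns `species` and `seq` (orthologous
#'   sequence windows), or a named character vector.
#' @param ref_species Name of the reference species (must be present).
#' @param ref_site_position 0-based position of the reference donor's `G`
#'   within the reference window.
#' @param model A `splice_model` for nine-base windows.
#' @param weak_threshold Score (bits) below which a GT site is called
#'   `weak`. Defaults to `mean - 2*sd` of `stats` when supplied, else 0.
#' @param stats Optional [donor_score_stats()] row used for the default
#'   threshold.
#' @param exon_lengths Optional named numeric vector (by species) of exon
#'   lengths measured from the window start, used to report whether the
#'   site is frame-compatible; species without an entry get `NA`.
#' @param align_params Named list overriding [map_homologous_site()]
#'   alignment scores.
#' @return Tibble with one row per species: `species`, `site_position`,
#'   `dinucleotide`, `has_site1`, `site1_score`, `in_frame`, and a
#'   list-column `gt_survey` of per-species [window_gt_survey()] tracks.
#' @export
site_conservation_table <- function(windows, ref_species, ref_site_position,
                                    model, weak_threshold = NULL,
                                    stats = NULL, exon_lengths = NULL,
                                    align_params = list()) {
  if (!is.data.frame(windows)) {
    windows <- tibble(species = names(windows), seq = unname(windows))
  }
  if (!ref_species %in% windows$species) {
    abort(sprintf("reference species '%s' not in windows", ref_species))
  }
  if (is.null(weak_threshold)) {
    weak_threshold <- if (!is.null(stats)) stats$mean - 2 * stats$sd else 0
  }
  ref_seq <- windows$seq[windows$species == ref_species][1]
  ap <- modifyList(list(match = 1, mismatch = -1, gap_open = -4,
                        gap_extend = -1), align_params)
  rows <- purrr::map2(windows$species, windows$seq, function(sp, seq) {
    seq <- toupper(seq)
    pos <- if (sp == ref_species) as.integer(ref_site_position) else {
      map_homologous_site(ref_seq, ref_site_position, seq,
                          match = ap$match, mismatch = ap$mismatch,
                          gap_open = ap$gap_open, gap_extend = ap$gap_extend)
    }
    din <- if (!is.na(pos) && pos + 2 <= nchar(seq)) {
      substr0(seq, pos, pos + 2L)
    } else NA_character_
    score <- NA_real_
    if (!is.na(din) && din == "GT" && pos >= 3 && pos + 6 <= nchar(seq)) {
      score <- score_window(model, substr0(seq, pos - 3L, pos + 6L))
    }
    has <- if (is.na(pos) || is.na(din)) "no"
      else if (din != "GT") "gt_absent"
      else if (!is.na(score) && score >= weak_threshold) "yes"
      else "weak"
    in_frame <- NA
    if (!is.na(pos) && !is.null(exon_lengths) && sp %in% names(exon_lengths)) {
      in_frame <- frame_compatible(exon_lengths[[sp]], pos)
    }
    tibble(species = sp, site_position = pos, dinucleotide = din,
           has_site1 = has, site1_score = score, in_frame = in_frame,
           gt_survey = list(window_gt_survey(seq, model)))
  })
  bind_rows(rows)
}
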