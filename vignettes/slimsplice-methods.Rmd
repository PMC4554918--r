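---
title: "Models and methods behind slimsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slimsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimsplice)
```

slimsplice analyses how a multi-exon gene diversifies its protein output:
through the acquisition of short linear motifs (SLiMs), through splitting
of the encoding region into exons, and through alternative splicing that
varies the motif complement between isoforms. The model system is the
C-terminal interaction region of the NCoR-family co-repressors, where
CoRNR-box motifs sit in an intrinsically disordered region and one
exon-internal splice donor decides whether a CoRNR box is included. This
vignette documents the models, the tunable parameters and their defaults,
the synthetic data the package validates itself on, and the design
decisions a maintainer would want spelled out.

## Coordinates, gene models and splicing

All internal coordinates are 0-based half-open; GFF3 on disk is 1-based
inclusive, converted at the I/O boundary. This keeps interval arithmetic
free of off-by-one adjustments while files remain standard.

A `gene_model` holds labelled exons in transcription order with a strand
and a CDS start phase (bases at the region's 5' end completing a codon
begun upstream; the synthetic models use phase 0, and the phase is always
carried explicitly because exon-37 phases are generally not annotated for
this family). Every motif and splice analysis runs on the sense strand:
minus-strand exons are reverse-complemented before concatenation, and an
internal-donor cut index `c` always means "retain the first `c`
sense-strand bases of the exon". Internal donors are serialised either as
2-base `five_prime_cis_splice_site` features in the GFF3 or as a sidecar
TSV.

Splicing choices are binary per event: a cassette exon is included or
excluded whole; an alternative internal donor chooses the exon-terminal
("long", site 2) or internal ("short", site 1) donor. `spliced_cds()`
concatenates the retained segments; translation uses the standard genetic
code, halts at the first stop, and reports whether a stop was seen.
Frame-breaking choices are allowed but flagged (`frameshift = TRUE`)
rather than refused, so pathological configurations stay visible.

## Motif model

A SLiM pattern is an ordered list of allowed-residue sets
(`L/I.x.x.I/H.I.x.x.x.I/L` for the CoRNR box): no weights, no profile —
the motifs of interest are defined by consensus, and a binary match keeps
"complete" and "partial" calls crisp. A window matching all constrained
positions is a complete hit. A *partial* hit matches all constrained
positions except exactly one **key position**; by default the single key
position is the most C-terminal constrained one, because the
biologically meaningful degraded instances of the CoRNR box are those
lacking the conserved terminal leucine/isoleucine. Which positions count
as key is configurable per pattern (third column of the pattern file),
since reasonable people could also accept mismatches elsewhere.
Overlapping hits are all reported; greedy masking could hide pathology
and CoRNR boxes do not overlap in practice.

Positions reported to users (`mismatched_positions`, `key_positions`) are
1-based, following R convention; hit coordinates (`start`, `end`) are
0-based half-open like all other intervals.

SANT domains are deliberately *not* detected: the family-membership rule
takes a `sant_count` argument, because SANT annotation is best taken from
existing domain databases rather than re-derived from a toy matcher. The
rule itself — at least two complete CoRNR hits, a SHARP hit after all
CoRNR hits that is also the most C-terminal hit, and at least two SANT
domains — returns the list of failed clauses rather than a bare reject.

The shipped pattern file contains the CoRNR consensus and a SHARP pattern
that is an illustrative synthetic stand-in (the real SHARP consensus is
not redistributed); both are plain text and user-editable.

## Donor windows and scoring models

A donor window is nine bases: the last three exonic bases, then six
intron-side bases, with the GT at window positions 4–5. A nine-base
window cannot literally centre a dinucleotide; this 3+6 split is the
convention of the widely used maximum-entropy donor scorer, and is what
"centred on the GT" is taken to mean here. Windows containing `N` are
flagged invalid and never scored — a partially ambiguous window would
otherwise silently score as something it is not.

Scores are in bits: `log2(P_model(w) / P_background(w))`. The background
is an independent base-frequency model (uniform by default); a decoy
model can be attached to score against an empirical negative set instead.

**PWM.** Per-position frequencies with additive smoothing
`(count + α)/(n + 4α)`, default `α = 0.5` — chosen for stable
small-sample behaviour; the upstream literature does not fix a value.

**Maximum entropy.** The model is the maximum-entropy distribution over
windows whose declared marginals match the (pseudocounted) empirical
marginals, fitted by iterative proportional fitting (IPF). Defaults
constrain all singletons plus adjacent pairs: nearest-neighbour
dependence is the dominant correlation in donor sites, and the factor
tables stay small. Three numerical choices matter:

- *Pseudocounts* are applied as `4α` uniform pseudo-windows rather than
  per-cell constants, so singleton and pair targets stay mutually
  consistent (IPF with inconsistent targets does not converge) and the
  singleton targets equal the PWM's frequencies exactly — which is what
  makes the singleton-only maxent model reproduce PWM scores to
  floating-point accuracy, a property the tests assert at 1e-6 bits.
- *Fitting* enumerates the `4^L` window space internally (262,144 states
  for L = 9; a guard refuses L > 10) but the model stores only the
  per-constraint factor tables plus a residual normalisation term;
  scoring is a sum of factor lookups.
- *Convergence* is the maximum absolute marginal discrepancy, default
  tolerance 1e-8, with an error (naming the worst constraint) rather
  than a silent cut-off on non-convergence.

A third model kind, `table`, wraps an externally produced
window-to-score map, so published donor score tables supplied by the
user reproduce their scores exactly; the package never downloads or
embeds such tables. Model files are plain text and round-trip
bit-exactly (`%.17g`).

Validated-donor statistics are the mean and sample SD (n−1) of the
scored donor list; at least two donors are required.

## The mutation scan

The scan enumerates every dinucleotide at Hamming distance 1 from GT —
`GA, GG, GC, AT, CT, TT` — plus, under a flag, existing GT sites
(distance 0), so a real internal donor can be surveyed with the same
machinery. Only GT-creating substitutions are considered; GC–AG and
U12-type AT–AC introns are out of scope. Each candidate's window is
built with the substitution applied; candidates within three bases of
the exon start, or short of right-side context, are flagged
(`insufficient_exonic_context` / `insufficient_flank`) but kept, never
silently dropped.

Candidates are standardised against the validated donors
(`z = (score − mean)/sd`) and the headline strong-site criterion is
`score > mean`; both the raw score and `z` are reported because it is
not knowable which scale a reader will prefer, and ranking is identical
under either. Ties sort by ascending position. Reading-frame
compatibility is `(exon_length − cut) mod 3 == 0`; the excised-segment
translation oracle in the tests confirms this exhaustively to length 60.
The companion `inframe_stop_scan()` asks whether skipping a donor runs
into a truncating in-frame stop shortly downstream — the signature that
makes an internal donor obligatory rather than alternative.

## Conservation of a donor site across species

The survey reports every context-complete GT in a window (115 bases by
default, centred on the reference site) with its score; overlapping GTs
are each reported. Cross-species anchoring uses global
Needleman–Wunsch alignment against the reference, one species at a time
(the comparison is reference-anchored, so a multiple alignment would add
cost without changing the question); default scores are match +1,
mismatch −1, gap open −4, gap extend −1 — declared defaults, not values
inferred from any particular dataset. The per-species call is: `yes`
(GT at the homologous position, scoring at least the weak threshold),
`weak` (GT in a poor-consensus context), `gt_absent` (position exists
but is not GT — the pattern of a paralogue that lost the site by point
mutation), `no` (position unalignable). The weak threshold defaults to
`mean − 2·SD` of the validated donors when statistics are supplied, else
0 bits; "poor consensus" has no published numeric cut, so the default is
stated rather than pretended to be derived.

## Isoform space

`k` binary events generate exactly `2^k` isoforms, ordered by binary
counting over events in input order. Isoform identity is the **choice
vector**, not the protein string: two choices yielding the same protein
remain distinct isoforms, matching transcript-level counting (16
isoforms from four alternatively spliced exons). Each isoform's motif
complement is simply a fresh scan of its translated protein — the tests
assert the stored complements equal recomputation from scratch.

## What the synthetic data emulates — and what it does not

`simulate_locus()` builds a 10-exon C-terminal region (labels 37–46)
with canonical `GT..AG` introns, three planted CoRNR boxes, a C-terminal
SHARP motif, and four binary events (the exon-37 internal donor plus
three cassette exons). Defaults, all in `extdata/locus_default.yaml`:

- *Donor model*: per-position weights approximating the vertebrate
  consensus `(C/A)AG|GTAAGT`, 70–90% on the consensus base, probability 1
  on the GT itself (validated donors carry GT by definition); the exact
  weights live in `extdata/donor_freq_default.tsv`, not in code.
- *Intron length*: 250 bases, the flank length used for this family's
  splicing-reporter constructs; a 97-base value mirrors the short
  zebrafish exon 36–37 spacing and can be set per intron.
- *Exon lengths*: multiples of 3, so planted features stay codon-aligned
  and every event's removed segment is frame-preserving. Real exons are
  under no such constraint; this is a deliberate simplification that the
  frameshift-flagging tests compensate for by constructing off-frame
  cuts explicitly.
- *Coding sequence*: random peptides back-translated with the first
  codon per amino acid — determinism over codon realism. Donor windows
  that would write a stop codon into coding sequence are
  rejection-sampled away.
- *The planted cryptic site* (the NCoR1-like variant) is a GA one
  substitution from a **strong** donor: the window is drawn from the
  donor model conditioned on scoring at least `internal_donor.min_bits`
  (default 12 bits against a uniform background, clearly above typical
  validated-donor scores). Unconditioned draws are frequently mediocre
  and would not implement the "strong donor" premise the recovery
  analyses rely on.

Passing tests on these data show that the machinery is correct — that
planted truths are recovered exactly, that estimators recover generating
parameters, that independent oracles agree. They do not show that real
donors follow the synthetic frequency model, that real exons are
codon-aligned, or that real splicing outcomes follow donor strength; the
biological literature shows the outcome is strongly context-dependent
(the same donor sequence splices differently in different species'
embryos), which is exactly why the package predicts site strength and
frame compatibility but never splicing outcome. Validation against real
sequences requires the user to supply them (and, for published-score
reproduction, a score table via `table_model()`); with such data one can
check, for example, that a scan of a real exon 37 reports the small
number of above-mean GT-convertible sites and the ~8-bit validated-donor
mean reported for *Xenopus* NCoR1.

## Degenerate inputs and edge behaviour

Empty FASTA files, non-amino-acid pattern tokens, out-of-range cut
indices, overlapping exons, unknown event keys and missing reference
species are all hard errors naming the offending record or token.
Windows with `N` are flagged, not scored; unscorable mutation candidates
sort last; a protein shorter than a pattern yields an empty hit table,
not an error. `parse_slim_pattern()` accepts an all-wildcard pattern
(it matches everywhere) even though such a pattern is useless, because
refusing it would complicate the grammar for no safety gain.

## Problem sizes used in the self-checks

The shipped validation runs at sizes chosen to make sampling error
negligible relative to the asserted tolerances while keeping a full run
in minutes on one core: 2,000 training windows for parameter recovery
(per-position total-variation ≤ 0.05), 10,000 for the sampling-accuracy
check (TV ≤ 0.03), 500 random 200-base exons for enumeration/brute-force
agreement, 100 random windows for the maxent/PWM limit (≤ 1e-6 bits), 50
seeded locus replicates for cryptic-site recovery (≥ 95% rank-1), 200
planted proteins for motif-status recovery, and the exhaustive frame
check to exon length 60.

## Known limitations

- No acceptor-site, branch-point or splicing-regulatory-element (ESE/ISS)
  models; no prediction of splicing outcome or isoform abundance.
- One gene model per gene id; no trans-splicing, non-canonical acceptors
  or multi-isoform GFF3 reconciliation.
- Maxent fitting enumerates `4^L`, so window length is capped at 10.
- Pairwise (not multiple) alignment anchors cross-species positions; very
  diverged windows may fail to map and are reported as `no`.
- The acquisition matrix summarises presence, not orthology: it does not
  distinguish a motif gained independently from one inherited.
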