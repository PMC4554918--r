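# Default synthetic locus: the 10-exon C-terminal region of an NCoR2-like
# co-repressor gene (exons 37-46), with an internal donor in exon 37
# defining the 37b sub-segment, three planted CoRNR boxes, a C-terminal
# SHARP motif and four binary alternative-splicing events.
#
# Exon lengths are multiples of 3 so planted features stay codon-aligned
# and every event's removed segment is frame-preserving.
gene_id: NCoR2syn
contig: chrSyn
strand: "+"
cds_start_phase: 0
exon_labels: ["37", "38", "39", "40", "41", "42", "43", "44", "45", "46"]
exon_lengths: [171, 120, 147, 105, 150, 93, 126, 114, 99, 150]
intron_length: 250
flank: 100
terminal_stop: true
# internal 5' splice donor of exon 37 ("site 1"); the terminal donor of the
# extended exon is "site 2". With gt: false the site carries a GA instead
# (the paralogue that lost splicing by point mutation) and is recorded as
# the planted cryptic site.
internal_donor:
  exon: "37"
  cut: 117
  gt: true
  # the site must look like a strong donor: its window is drawn from the
  # donor model conditioned on scoring at least this many bits over a
  # uniform background
  min_bits: 12
donor_model: default
motif_placements:
  - pattern: CoRNR
    instance: CoRNR1
    peptide: LEDHIRQAL
    exon: "37"
    nt_offset: 126
    status: complete
  - pattern: CoRNR
    instance: CoRNR2
    peptide: IADHISSTI
    exon: "39"
    nt_offset: 60
    status: complete
  - pattern: CoRNR
    instance: CoRNR3
    peptide: LQRHIAEGI
    exon: "41"
    nt_offset: 60
    status: complete
  - pattern: SHARP
    instance: SHARP
    peptide: GPSLQKL
    exon: "46"
    nt_offset: 120
    status: complete
events:
  - event_id: e37b
    kind: alternative_internal_donor
    exon_label: "37"
    cut_index: 117
  - event_id: e39
    kind: cassette_exon
    exon_label: "39"
  - event_id: e42
    kind: cassette_exon
    exon_label: "42"
  - event_id: e44
    kind: cassette_exon
    exon_label: "44"
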