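# TCR cytoplasmic tail definitions (residue scale).
#
# Indexing convention: residues are numbered 1..n_residues starting at the
# membrane anchor (juxtamembrane, N-terminal end); the anchor itself is bead 0,
# fixed on the membrane plane z = 0. One bead per residue, Kuhn length 0.3 nm.
#
# Provenance: chain lengths are those of the human TCR subunits (zeta 113,
# epsilon 55, delta 47, gamma 45 cytoplasmic residues). Tyrosine positions for
# zeta follow the model's printed landmarks (membrane-proximal tyrosine 21
# residues from the anchor, membrane-distal tyrosine 12 residues from the
# C-terminus, second-to-last tyrosine at residue 83); the remaining positions
# preserve ITAM-like paired spacing. Basic-residue (Lys/Arg) positions are an
# approximate reconstruction from the canonical human sequences; the epsilon
# tail carries 14 basic residues, concentrated in the juxtamembrane
# basic-rich stretch, with its two tyrosines clumped at the distal end.
# itam_centers are the midpoint residue of each tyrosine pair (rounded down).
chains:
  - name: zeta
    n_residues: 113
    kuhn_length: 0.3
    sites: [21, 32, 60, 72, 83, 101]
    site_kind: tyrosine
    itam_centers: [26, 66, 92]
    basics: [1, 3, 6, 28, 29, 37, 38, 39, 41, 48, 50, 51, 52, 64, 66, 77, 80, 81, 82, 84, 98]
  - name: epsilon
    n_residues: 55
    kuhn_length: 0.3
    sites: [36, 47]
    site_kind: tyrosine
    itam_centers: [41]
    basics: [1, 3, 4, 6, 8, 12, 19, 21, 25, 27, 40, 41, 44, 53]
  - name: delta
    n_residues: 47
    kuhn_length: 0.3
    sites: [23, 34]
    site_kind: tyrosine
    itam_centers: [28]
    basics: [2, 7, 17, 36, 46]
  - name: gamma
    n_residues: 45
    kuhn_length: 0.3
    sites: [23, 34]
    site_kind: tyrosine
    itam_centers: [28]
    basics: [4, 9, 19, 38, 44]
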