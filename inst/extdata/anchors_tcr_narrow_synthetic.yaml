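# Membrane-anchor layout for the six-chain TCR assembly ("tcr-narrow").
#
# SYNTHETIC idealisation guided by the cryo-EM receptor geometry: the six
# cytoplasmic chains emerge from the membrane within a narrow footprint with
# nearest-neighbour anchor spacing of about 1.5 nm. Anchors are placed evenly
# on a circle of radius 1.5 nm (giving exactly 1.5 nm nearest-neighbour
# spacing); these are not coordinates extracted from a structure file.
# Chain order interleaves the long and short chains around the circle.
layout:
  name: tcr_narrow
  chains: [zeta, epsilon, delta, zeta, epsilon, gamma]
  anchors:
    - [1.5, 0.0, 0.0]
    - [0.75, 1.299038105676658, 0.0]
    - [-0.75, 1.299038105676658, 0.0]
    - [-1.5, 0.0, 0.0]
    - [-0.75, -1.299038105676658, 0.0]
    - [0.75, -1.299038105676658, 0.0]
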