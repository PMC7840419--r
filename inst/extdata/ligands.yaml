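# Globular binding partners, modelled as hard spheres.
# Radii follow sphere-equivalent volumes of the relevant domains
# (protein density 1.41 g/cm^3): LCK kinase domain 2.1 nm (7 Kuhn lengths),
# ZAP70 tandem SH2 2.7 nm (9 Kuhn lengths), CD45 phosphatase domains 3.4 nm
# (11 Kuhn lengths).
ligands:
  - name: LCK
    radius: 2.1
    role: kinase
  - name: ZAP70
    radius: 2.7
    role: reader
  - name: CD45
    radius: 3.4
    role: phosphatase
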