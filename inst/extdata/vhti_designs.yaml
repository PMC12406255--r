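# Grafting design config: pepitem epitope variants spliced into the VhTI
# scaffold variant (27 aa, Z = norleucine at position 6, Ac/amide termini,
# two disulfides I-IV, II-III).
#
# Spans are 1-based inclusive on the evolving sequence of each design; the
# published "residues 9-14" replacement is stated on this 27-residue
# synthesized variant numbering. VhTI-pep 1 and 2 retain Ala9 and replace
# 10-14; VhTI-pep 3-5 replace 9-14; VhTI-pep 6 grafts the full pepitem
# sequence across both helices and the loop as three sequential splices.
scaffold:
  sequence: EQCKVZCYAQRHSSPELLRRCLDNCEK
  n_term: acetyl
  c_term: amide
  n_disulfides: 2
reference:
  pepitem: SVTEQGAELSNEER
designs:
  - name: VhTI-pep 1
    steps:
      - span: [10, 14]
        insert: QGAELS
  - name: VhTI-pep 2
    steps:
      - span: [10, 14]
        insert: QGAEL
  - name: VhTI-pep 3
    steps:
      - span: [9, 14]
        insert: EQGAEL
  - name: VhTI-pep 4
    steps:
      - span: [9, 14]
        insert: QGAELS
  - name: VhTI-pep 5
    steps:
      - span: [9, 14]
        insert: EQGALS
  - name: VhTI-pep 6
    steps:
      - span: [4, 6]
        insert: SVT
      - span: [8, 14]
        insert: EQGAEL
      - span: [15, 19]
        insert: SNEER
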