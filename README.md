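# ScaffoldMatch

Structure-guided scaffold matching and molecular grafting for stabilized
peptide probes, in R.

Short linear peptides with useful bioactivity — such as pepitem, the
14-mer `SVTEQGAELSNEER` released from the 14-3-3ζ protein, an endogenous
inhibitor of lymphocyte transendothelial migration — are typically
unstructured in solution and degrade within hours in serum. Inside the
parent protein the same sequence folds as a helix–loop–helix (HLH). The
grafting strategy is to find a small, naturally rigid peptide with the
same backbone shape — here the α-hairpinin trypsin inhibitor VhTI, whose
two helices are stapled by disulfides with connectivity I–IV, II–III —
and splice the bioactive epitope into its loop.

`ScaffoldMatch` implements the desk side of that workflow for structural
bioinformaticians and peptide engineers:

* **Structure IO** — PDB/mmCIF parsing into a uniform polymer model
  (author numbering plus gap-free `label_id`), PDB output.
* **Secondary structure** — Cα-only, P-SEA-style distance-window
  assignment (`H`/`E`/`C`), usable on backbone-sparse peptide entries.
* **Motifs & curation** — HLH motif extraction, Sγ-distance disulfide
  detection with Roman-numeral connectivity, the 10–50 residue / ≥2 Cys
  scaffold filter with reason codes, sequence-level deduplication.
* **Superposition** — Kabsch (SVD, det +1) rigid superposition;
  framework-constrained alignment that fits helices only (sliding-window
  joint offset optimization, loop left free); a CE-style
  sequence-independent fragment aligner; candidate ranking by RMSD.
* **Grafting** — chimera construction by sequence splicing
  (`scaffold[1:s-1] + insert + scaffold[e+1:n]`), register enumeration,
  N-acetyl / C-amide / norleucine bookkeeping; the packaged config
  rebuilds the published VhTI-pep 1–6 series exactly.
* **Masses** — monoisotopic and average [M] and [M+H]⁺ of modified
  peptides (acetyl +42.01057, amide −0.98402, −2.01565 per disulfide,
  Z = norleucine = C6H11NO).
* **Conservation** — per-column frequency/entropy/information-content
  profiles of pre-aligned homolog sets, logo matrix export.
* **Assay statistics** — three-parameter dose–response EC50 with top
  fixed at 100 and slope 1; one-phase serum-decay half-life with
  censoring (">48"); TEER; apparent permeability; migration
  normalizations.
* **Synthetic generators** — seeded HLH fixtures with planted disulfide
  staples, truth-tabled scaffold libraries, dose–response/decay series,
  and conservation-controlled alignments, used throughout the tests.

## Worked example

```r
library(ScaffoldMatch)

## build the published graft series from the packaged config
ds <- vhtiDesigns()
peptideSequence(ds[["VhTI-pep 2"]])
#> [1] "EQCKVZCYAQGAELPELLRRCLDNCEK"

computeMass(ds[["VhTI-pep 6"]]@chimera)
#> MassResult: mono M = 2950.1837, mono [M+H]+ = 2951.1910, avg M = 2952.149, avg [M+H]+ = 2953.157 Da

## scaffold matching on a synthetic fixture
fx <- buildHLH(hlhRecipe(helix1 = 10, loop = 5, helix2 = 10))
assignSecStruct(fx$structure, "A")
#> SecStructAssignment chain A (25 residues)
#>   HHHHHHHHHHEEEEEHHHHHHHHHH

cand <- buildHLH(hlhRecipe(10, 5, 10, noise_sigma = 0.3, seed = 7,
                           transform = TRUE))
frameworkAlign(fx$structure, fx$motif, cand$structure, cand$motif)
#> SuperpositionResult (framework): rmsd = 0.271 A over 20 residues

## dose-response fitting on simulated migration data
d <- simulateDoseResponse(ec50 = 10, bottom = 60, sigma = 5, seed = 1)
fitEC50(d$concentration, d$response)
#> DoseResponseFit: EC50 = 11.35, bottom = 59.7, top = 100, slope = 1
```

The mass printed for VhTI-pep 6 (monoisotopic [M+H]⁺ 2951.19 Da) and for
the VhTI scaffold variant (3258.54 Da) match the published calculated
values 2951.2 and 3258.5. The framework RMSD reports the conformational
fit over helix residues only, leaving the grafted loop free — the
quantity used to rank scaffold candidates.

A thin command-line front end ships in `exec/scaffoldmatch.R`
(subcommands `inspect`, `secstruct`, `curate`, `match`, `graft`, `mass`,
`conserve`, `simulate`, `fit-ec50`, `fit-decay`, `teer`, `papp`, `run`):

```sh
CLI=$(Rscript -e 'cat(system.file("exec/scaffoldmatch.R", package="ScaffoldMatch"))')
Rscript "$CLI" run --out report/ --seed 1
```

`run` executes curate → match → graft → mass on a (synthetic or supplied)
library and writes `candidates.tsv`, `ranked.tsv`, `designs.fasta`,
`masses.tsv` and a checksummed `manifest.json`.

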