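---
title: "Structure-guided scaffold matching and peptide grafting"
author: "ScaffoldMatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided scaffold matching and peptide grafting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ScaffoldMatch)
```

## The problem

A short linear peptide that inhibits lymphocyte transendothelial migration
(pepitem, the 14-mer `SVTEQGAELSNEER` released from the 14-3-3ζ protein)
is unstructured and rapidly degraded in serum. Inside its parent protein,
however, the same sequence adopts a helix–loop–helix (HLH) conformation.
The engineering strategy this package supports is *molecular grafting*:
find a small, naturally rigid peptide whose backbone matches that
conformation — here an α-hairpinin trypsin inhibitor (VhTI) whose two
helices are stapled by disulfides with connectivity I–IV, II–III — and
splice the bioactive epitope into its loop, inheriting the scaffold's
stability.

The package implements the desk side of that workflow end to end: parsing
structures, assigning secondary structure from Cα geometry, extracting HLH
motifs and disulfide connectivity, curating and ranking scaffold libraries
by framework-constrained superposition, enumerating grafted chimeras with
terminal modifications, computing their masses, profiling epitope
conservation, and fitting the downstream assay statistics. Everything runs
from files and seeds; no live database, structure prediction or wet-lab
input is required.

## Secondary structure from Cα geometry

Many peptide NMR and X-ray entries lack complete backbones, so assignment
uses Cα distances only (in the spirit of P-SEA). A 5-residue window
starting at residue $i$ is *helix-compatible* when

$$d_{i,i+2} \in [5.0, 6.0],\quad d_{i,i+3} \in [4.8, 5.8],\quad
  d_{i,i+4} \in [5.8, 7.0] \ \text{Å}.$$

A residue *seeds* a helix when at least 3 of the 5 windows covering it
pass; seeded runs then extend outward over residues covered by at least
one passing window, and runs shorter than 4 residues are demoted to coil.
The two-stage rule is deliberate: window support necessarily thins at
helix termini (a window must lie entirely inside the helix to pass), so a
pure 3-of-5 vote systematically clips 2–4 residues from every helix end
— enough to shrink a 10-residue helix below any useful recovery rate —
while a pure 1-of-5 union rule loses the vote's robustness against
single-window dropouts in noisy interiors. Residues with
$d_{i,i+2} \in [6.6, 7.4]$ Å and a near-straight Cα pseudo-bond angle
(≥120°) are labeled extended; everything else is coil. All thresholds are
exposed in `secstructParams()`.

A practical floor follows from the window length: helices of 4 residues
satisfy the motif definition but contain no complete 5-residue window and
are therefore undetectable from distances alone; detection effectively
starts at 5–6 residues. Library entries at the 9–10 residue filter
boundary are curated by length and cysteine count only.

## Motifs, disulfides and curation

Maximal helix runs separated by a non-helix gap of 1–12 residues form an
HLH motif (beyond ~12 residues two helices no longer form one "turn";
the cap is configurable). Disulfides are detected from Sγ–Sγ distances
(≤2.3 Å: the canonical 2.05 Å bond plus slack), falling back to Cβ–Cβ
(≤4.5 Å) for partial models, with greedy nearest-first pairing; cysteines
are numbered I, II, … by sequence position to produce the conventional
connectivity string ("I–IV, II–III" for the α-hairpinin staple). The
curation filter passes chains of 10–50 residues (both bounds inclusive)
with ≥2 cysteines and reports machine-readable failure reasons;
deduplication keeps one candidate per identical sequence, preferring the
lexicographically smallest source id.

## Superposition and ranking

`kabsch()` is the standard SVD solution for the least-squares rigid
transform with the determinant sign correction (never a reflection); the
test suite cross-checks it against an independently implemented
quaternion-eigenvalue (Horn) oracle.

`frameworkAlign()` is the scaffold-matching score: the correspondence is
built *only* from helix residues (helix1↔helix1, helix2↔helix2,
order-preserving — the scaffolds of interest align N→C), the shorter
helix slides along the longer, and the pair of offsets minimizing the
joint Kabsch RMSD is chosen by exhaustive enumeration (offset ranges are
tiny for peptides, so no heuristic is needed). Loop residues are excluded
from the fit — the whole point of the constraint is to leave the grafted
loop conformationally free — but a post-transform loop RMSD is reported
when loop lengths match.

`ceStyleAlign()` is a sequence-independent combinatorial-extension-style
aligner over 8-residue fragment pairs whose intra-fragment distance
matrices agree within 3.0 Å on average. The chaining dynamic program
maximizes aligned length with the cumulative intra- *plus* inter-fragment
dissimilarity as tie-breaker; the inter-fragment term matters because on
internally periodic structures (helices) intra-fragment distances cannot
distinguish register, and without it register-shifted paths tie with the
correct one. Reproducing any particular program's numbers is a non-goal;
the published 2.55 Å framework fit for the 14-3-3ζ fragment against VhTI
is accepted within ±0.5 Å because that number is algorithm-specific.

Ranking sorts candidates by ascending RMSD, ties broken by aligned length
(longer first) then source id, and skips motif-free candidates with a
logged reason.

## Grafting and masses

Designs are sequence-level objects: a scaffold `PeptideSpec` (sequence
with `Z` for norleucine, terminal states, disulfide count) and splice
steps `(span, insert)` on the evolving sequence, applied by
`buildChimera()`. The packaged YAML config reproduces the published
VhTI-pep 1–6 series, including the multi-span graft (pep 6) as three
sequential steps. Register enumeration takes contiguous
`(offset, length)` windows into the epitope; one published variant
(`EQGALS`) carries an internal deletion and is therefore expressed as a
direct splice in the config rather than as a window.

Masses are computed from frozen residue tables (monoisotopic and average),
with N-acetylation +42.01057 Da, C-amidation −0.98402 Da, −2.01565 Da per
disulfide, proton 1.00728 Da, and norleucine massed as C6H11NO (the
leucine composition — it is the Met bioisostere with one fewer sulfur).
The published calculated-mass column is internally inconsistent by
~0.1 Da: two rows match standard monoisotopic [M+H]⁺ to 0.05 Da while the
remainder sit ~0.1 Da below it (their convention is not stated). The
package reports standard monoisotopic values and documents a 0.2 Da
regression tolerance against the full column rather than guessing the
convention row by row.

## Conservation profiling

For a pre-aligned homolog set, each column yields residue frequencies
(gaps tallied separately and excluded from entropy), Shannon entropy $H$
in bits over the renormalized non-gap distribution, information content
$IC = \log_2 20 - H$ clipped at 0, and the alphabetically tie-broken
consensus. Both bit heights (frequency × IC) and plain frequency heights
are exportable, since logo conventions differ; a WebLogo-style
small-sample correction ($e_n = 19/(2 n \ln 2)$) is available but off by
default. Homolog retrieval and alignment construction are out of scope —
the synthetic generator produces alignments with controlled per-column
conservation instead.

## Assay statistics

* **Dose–response**: $Y = b + (100 - b)/(1 + 10^{\log_{10} c -
  \log_{10} EC_{50}})$, top fixed at 100 % of the untreated control and
  Hill slope fixed to 1, fitted by Levenberg–Marquardt least squares in
  $\log_{10}$ concentration from a deterministic 5-point EC50 start grid
  (the surface is mildly multimodal in $\log EC_{50}$; the grid is
  seedless and cheap). Replicates are pooled unweighted. Data flat at
  control level (depth < 5 %) are reported as not converged rather than
  fitted.
* **Serum decay**: one-phase decay $Y = (y_0 - p)e^{-kt} + p$ with the
  plateau bounded in [0, 100] %; half-life $t_{1/2} = \ln 2 / k$.
  Non-decaying series are flagged and, when the last point is still
  ≥80 %, labeled censored (">48" style) instead of being forced through
  the model.
* **Barrier assays**: TEER $= (\Omega_{mono} - \Omega_{blank}) \times$
  area (Ω·cm²; negative values are returned but flagged) and
  $P_{app} = C_{abl} V_{abl} / (A\, C_{lum}\, t)$ in cm/s with the
  receiver volume in cm³.
* **Migration normalizations**: percent inhibition
  $100(1 - T/U)$ against the untreated control (negative = enhanced
  migration) and the migration index $T/R$ against the reference-peptide
  control.

## What the synthetic generators emulate

`buildHLH()` produces canonical helices (1.5 Å rise, 100°/residue,
2.3 Å radius) joined by a circular-arc loop whose Cα spacing stays within
3.8 ± 0.2 Å, with planted Sγ staples at exactly 2.05 Å. `noise_sigma` is
the **RMS positional displacement** per atom (the usual crystallographic
"coordinate error" convention), i.e. per-axis SD `noise_sigma/sqrt(3)`;
this is the reading under which a 0.3 Å noise level produces ~0.3 Å
superposition RMSD, as it should. Fixtures are geometrically plausible,
not biophysically realistic: no side chains beyond Cβ/Sγ, no loop
ensembles, no packing. Passing closed-loop tests therefore demonstrates
that the geometry pipeline recovers planted ground truth under controlled
noise — not that it reproduces the quirks of deposited experimental
models (missing residues, alternate conformers beyond occupancy ties,
lattice contacts).

Simulation defaults encode the study conditions. Dose–response draws use
an 8-point half-log dilution series with the EC50 mid-series and 5
independent replicates per concentration (migration EC50s in this setting
are averaged over 3–5 independent experiments; a single-replicate series
at 5 % noise is formally insufficient to pin a slope-1 EC50 to better
than ~30 %). Decay series use 8 time points to 48 h in duplicate
(serum-stability determinations here are n = 2). The ranking-monotonicity
experiment uses a geometric noise ladder (0.05 × 1.45ⁱ Å): RMSD
estimates at adjacent linear noise steps overlap statistically, so a
discriminable ladder is required to test ordering at all.

Test problem sizes are deliberately desk-scale: 100 noisy fixtures for
label recovery, 1000 instances for the Kabsch/quaternion cross-check, a
20-entry truth-table library, 50/100 seeds for the fit-recovery
experiments — each chosen as the smallest size at which the property is
statistically meaningful.

## Numerical and design choices

* Altlocs resolve to highest occupancy, ties by file order; insertion
  codes are distinct residues in file order; non-standard residues with a
  Cα are retained (`X`, with NLE → `Z`) so grafted peptides round-trip.
* Author numbering is reported wherever results reference published
  residue numbers; all internal indexing is the gap-free per-chain
  `label_id`, and each reported span states its convention.
* Collinear Kabsch inputs are flagged `ill_conditioned` rather than
  rejected (the RMSD is still well defined; the rotation is not unique).
* Disulfide pairing conflicts (one cysteine within threshold of two
  partners) are resolved nearest-first with a warning — at 2.3 Å they are
  geometrically pathological.
* The 14-3-3ζ entry used for the query fragment is a homodimer with
  identical chains; chain choice is an explicit argument everywhere, and
  the command-line interface refuses to guess.
* The command-line front end (`exec/scaffoldmatch.R`) is a thin
  dispatcher over exported functions; the R API is the primary surface.

## Known limitations

* No DSSP-style hydrogen-bond model and no π/3₁₀ subtypes; helices
  shorter than 5 residues are invisible to the distance windows.
* No flexible/torsional alignment, no TM-score, no all-atom RMSD.
* Sequence-level disulfide counts are metadata, not inferred from
  structure, so a design's count is only as good as its config.
* The local library curation stands in for a live structure-database
  similarity search; database hit counts are inherently irreproducible
  offline.
* EC50s and half-lives from real assays carry biological variance far
  exceeding fit error; simulation recovery says nothing about assay
  reproducibility.
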