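---
title: "Designing retro-inverso d-peptides by mirror-image fragment search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing retro-inverso d-peptides by mirror-image fragment search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridesign)
```

## The problem

Peptide agonists of class B GPCRs such as GLP-2 are short alpha helices
whose activity is dominated by a handful of hotspot side chains, but
they are degraded within minutes by serum proteases.  A d-peptide built
entirely from D-amino acids resists proteolysis, yet it cannot simply be
the same sequence in D-form: a D-helix presents its side chains as the
mirror image of the parent.  The retro-inverso idea is to search for
D-fragments whose side chains *reproduce the spatial arrangement of the
parent's hotspots*, then splice those fragments into one d-peptide.
Because reflecting a structure database (a "d-PDB") turns every deposited
L-protein into a valid D-protein, fragment geometry for D-peptides can be
mined from known structures.

`ridesign` implements that pipeline: segment the scaffold helix, define
hotspot-based structural queries at several atom levels, scan a mirrored
fragment library by least-squares superposition, and assemble the best
per-segment matches into a single d-peptide model.

## The model and its steps

### 1. Scaffold segmentation and hotspots

The scaffold (for GLP-2, the receptor-bound helix, residues 1--31) is
divided into three overlapping segments: helix1 = 1--14, helix2 = 7--19,
helix3 = 15--31.  Hotspots are user input, taken from prior mutagenesis:
H1, F6, E9 (helix1), D8, L14, L17 (helix2) and D21, F22, W25 (helix3).
`define_hotspots()` validates that each hotspot exists in its segment
with the expected residue type; shorter fragments are easier to match in
a library, while the overlaps leave room to place the splice points.

### 2. Atom-level queries

A query is an ordered set of hotspot atoms with scaffold coordinates.
Requiring every side-chain atom to match is too strict; using only CA
atoms is too permissive.  The default scheme therefore defines, per
hotspot, levels of increasing detail:

* level 1: `CA`
* level 2: `CA, CB`
* level 3: `CA, CB` + a side-chain *tip* (Phe `CG,CZ`; Trp `CG,CH2`;
  Asp `CG,OD1`; Glu `CD,OE1`; Leu `CG,CD1`; His `CG,NE2`)
* His only, level 4: the full imidazole anchor `CA, CB, CG, ND1, NE2`.

`enumerate_queries()` emits the Cartesian product of the per-hotspot
levels, in lexicographic order of the level indices.  For the GLP-2
hotspots this yields 4 x 3 x 3 = 36 queries for helix1 and 3 x 3 x 3 =
27 each for helix2 and helix3.  The level definitions are this package's
reconstruction, calibrated so that exactly these combination counts
arise; they are fully overridable through the `scheme` argument or the
YAML config.  Queries with fewer than three atoms are rejected because
rigid superposition would be under-determined.

### 3. The mirror transform and chirality audit

`mirror_structure()` negates one coordinate (default plane `"xy"`,
negate z).  Any reflection plane is equivalent up to a proper rotation;
one is fixed for reproducibility.  Reflection preserves every
interatomic distance exactly, so covalent geometry needs no
re-idealization, and it flips the chirality of every residue.
Handedness is called from the signed volume `det[N-CA, C-CA, CB-CA]`,
which is about +2.5 cubic Angstroms for L-residues in standard geometry
(the reference sign was measured on deposited L-protein structures);
glycine is achiral and residues missing any of the four atoms are
reported indeterminate rather than raising an error.

### 4. Search in the d-frame

One design decision deserves emphasis: **the query is reflected once
into the library's mirror frame, and library windows are fitted onto the
mirrored query using proper rotations only** (`superpose()`, a Kabsch
solver with a determinant correction).  Fitting the un-mirrored L-query
directly onto D-windows would ask a proper rotation to realize an
improper congruence, which is impossible except for planar atom sets —
the fit would never reach zero even for a perfect mirror copy.  In the
d-frame the perfect copy scores exactly zero and, by the reflection
conjugation identity (mirroring both point sets leaves the
proper-rotation RMSD unchanged), the reported value still equals the
RMSD between the l-query and the back-mirrored window.  The reported
match RMSD is `sqrt(mean(per-atom squared deviation))` after the optimal
fit.

Windows are all contiguous runs of the query's span length in every
mirrored chain, scanned **forward** (window residue order parallel to
the scaffold segment) and **reverse** (antiparallel).  The reverse
direction is the retro case: a D-fragment whose chain runs opposite to
the scaffold is exactly what a retro-inverso analogue needs, and because
queries use only CA/CB/side-chain atoms, the N/C backbone role swap of
retro matching never enters the correspondence.  This offset-respecting
correspondence is a deliberate simplification of fully order-independent
alignment: hotspot queries lie along one helix, so the only physically
distinct correspondences are the two directions.

Windows missing a required atom are skipped (`missing_atom`), as are
windows failing the optional residue-identity filter (`identity`); skip
reasons are counted and reported.  Each window keeps its best RMSD over
all query combinations (the per-segment profile pools query variants),
and the profile is sorted ascending with deterministic tie-breaking
(entry id, then start offset, then direction) and truncated to `top_k`
(default 1000).  Whether the original search required residue identity
at hotspot positions is unknown; both modes are provided and identity is
off by default, letting side-chain-atom RMSD do the selection.

One consequence of min-pooling across atom levels is worth knowing:
RMSDs from queries of different sizes are not directly comparable.  A
three-CA query fits almost any helix to a fraction of an Angstrom, so in
a pooled profile the least specific combination tends to set every
window's score.  When discrimination matters — as in the planted-match
validation — search with a single high-detail query (or enable the
identity filter), and treat pooled profiles as a recall-oriented view.

### 5. Placement and assembly

`place_match()` applies the stored rotation/translation to the full
window, so the hotspot-aligned atoms overlay the mirrored scaffold
hotspots with residual equal to the match RMSD (an invariant the tests
assert).  `assemble_peptide()` then splices one placed fragment per
segment.  The default plan cuts each overlap at its midpoint (ties
toward the N-terminal fragment): overlaps 7--14 and 15--19 give
crossovers after scaffold positions 10 and 17, hence contributions
1--10, 11--17, 18--31.  The assembled chain is written in retro
orientation — assembled residue 1 realizes scaffold position 31 — so
that reverse-direction (retro) matches contribute residues in their
native N-to-C order and the spliced backbone stays chemically
continuous.

Junction chemistry is *not* rebuilt: consecutive-residue C--N distances
outside 1.2--1.5 Angstroms are flagged in the geometry report (with a
warning, not an error), steric clashes are counted as non-bonded atom
pairs closer than 2.0 Angstroms between residues at least two apart in
the chain, and handedness uniformity is checked.  Refinement of the
junctions belongs to downstream simulation tools and is out of scope.

## Synthetic fixtures: what they emulate and what they do not

`build_ideal_helix()` places backbone atoms from standard internal
coordinates at ideal alpha-helical dihedrals (phi = -57, psi = -47,
omega = 180 degrees), plus CB and, for the six hotspot-capable residue
types, side-chain atoms out to the tips the default scheme needs, at
fixed idealized torsions.  D-handedness negates every torsion, giving
the exact mirror-image internal geometry.  `plant_match()` hides a
mirrored, noise-perturbed, rigidly displaced copy of a query's source
segment among decoy helices whose backbone dihedrals are jittered
uniformly by +/-10 degrees per residue — without that jitter all ideal
helices are exactly congruent at CA level (helical screw symmetry) and
CA-only recovery would be meaningless.  Rigid displacements sample
rotations uniformly (quaternion method) and translations in a 20
Angstrom box; all randomness is seed-local, so fixtures are
byte-reproducible.

These fixtures exercise every pipeline stage without downloads, but they
are idealizations: real helices bend, rotamers vary, libraries contain
loops and strands, and crystallographic coordinates carry experimental
error.  Passing the planted-recovery and self-reconstruction tests shows
the machinery is correct, not that real-library matches will reach any
particular RMSD.

## Numerical choices and degenerate inputs

* Superposition requires at least 3 points and rejects collinear sets
  (relative singular-value threshold 1e-8) as ill-posed.
* The proper-rotation constraint is enforced by flipping the sign of the
  smallest singular vector pair when the cross-covariance determinant is
  negative; reflections are never allowed in the solver, since an
  improper fit would silently undo the library mirror.
* Alternate locations resolve to the highest occupancy, ties broken
  alphabetically by altloc id.  Insertion codes are rejected with a
  clear error (intended inputs are simple peptide chains).  HETATM
  records are excluded; hydrogens are kept but flagged.
* Adding atoms to a query can lower its root-*mean*-square deviation
  (a perfectly matching extra atom dilutes the mean), but never the
  residual *sum of squares*; the monotonicity test asserts the
  sum-of-squares form.
* PDB files carry three decimal places, so any result that passes
  through files is reproducible only to about 1e-3 Angstroms; exactness
  claims (such as the self-reconstruction of a scaffold from its own
  mirrored segments, which recovers the scaffold mirror to ~1e-14 at CA
  level) hold for the in-memory composition.
* All pipeline stages are deterministic; identical configs give
  byte-identical outputs.  Randomness exists only in the fixture
  generators and is always seeded.

## Problem sizes used in the checks

The bundled tests run the whole pipeline on desk-scale synthetic data:
the 31-residue GLP-2 scaffold, self-libraries of its three segments,
decoy libraries of 50 jittered helices for planted-match recovery (20
seeds at noise 0.3 Angstroms), 100-seed noise-bound checks without
decoys, brute-force search equivalence on libraries under 200 windows,
and profile capping on a ten-chain library yielding 1040 windows.  These
sizes were chosen so the full suite completes in well under five minutes
on a single CPU while still exercising every code path at meaningful
scale.

## Known limitations

* PDB input only; mmCIF is not parsed.
* No nucleic acids, waters, ligands, insertion codes, or multi-model
  averaging (one model is selected by index).
* The atom-level scheme is a calibrated reconstruction, not the original
  definition table, which is not public; only the combination counts
  constrain it.
* Matching is offset-respecting (two directions), not fully
  order-independent; queries spanning non-collinear hotspot arrangements
  from several secondary-structure elements would need a general
  aligner.
* No receptor modelling, molecular dynamics, free-energy estimation or
  junction minimization: the output is a geometric model with provenance
  and a geometry report, intended as the input to such tools.
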