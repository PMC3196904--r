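---
title: "Modelling ice nucleation proteins: repeats, solenoids, ordered water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ice nucleation proteins: repeats, solenoids, ordered water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inphelix)
```

# The model

Bacterial ice nucleation proteins carry a central domain of tandem
16-residue repeats with the consensus `GYGSTxTAxxxSxLxA`. `inphelix`
treats one repeat as one coil of a parallel β-solenoid and derives
everything else from that correspondence:

* the **TxTA** and **xLxA** tetra-peptides are β-strands on the two
  opposite faces of the solenoid (the ice-nucleating surfaces, with the
  solvent-exposed Thr/Ser at strand positions 1 and 3);
* the **GYGS** and **xxxS** tetra-peptides are the connecting corners;
* register 12 (xxxS position 4) points inward and stacks into the serine
  ladder, register 6 (TxTA position 2) points inward and stacks into the
  glutamine ladder when the residue is Gln, and register 2 (GYGS
  position 2) points outward and stacks into the solvent-exposed
  tyrosine ladder that mediates dimerization;
* a parallel dimer is the 180° rotation of the chain about the long axis,
  tyrosine ladders facing, which places the SLTA face of one chain beside
  the TQTA face of the other and creates two flat composite surfaces;
* each flat surface can organise water into a net commensurate with the
  oxygen net of the primary prism plane of hexagonal ice
  (a ≈ 4.5 Å, c ≈ 7.35 Å at d(O–O) = 2.76 Å);
* the ice-active area is the plain rectangular footprint
  `length × width × n_faces`, compared against the ~20,100 Å² critical
  ice-embryo area at −12 °C. The package deliberately keeps this
  arithmetic (no solvent-accessible-surface refinement), because the
  quantity of interest is the flat template area seen by a nascent ice
  embryo.

# The coil template and backbone placement

The builder is template-free and parametric. Its cross-section is a
closed equilateral 16-gon of C-alpha positions (all chords 3.804 Å, the
virtual C-alpha spacing of an ideal trans backbone) with a 0.3 Å rise per
residue, i.e. 4.8 Å per coil:

* the two strands are planar zigzags with 3.37 Å advance per residue and
  0.88 Å pleat half-amplitude, placed on the +x and −x faces so the pleat
  peaks (registers 5/7 and 13/15) point outward;
* the two turns are four-residue arcs related to each other by the C2
  symmetry of the coil; their five edge directions were solved once for
  exact ring closure under shape constraints (face width ~20 Å,
  sheet-to-sheet thickness ~10 Å, no cross-ring contacts) and are frozen
  in `R/helix-constants.R`.

Backbone N and C atoms are placed from per-register offsets expressed in
the intrinsic frame (tangent, bisector, binormal) of the C-alpha trace.
The strand offsets were solved so that strand residues reproduce ideal
β-strand torsions (φ ≈ −124°, ψ ≈ +127°, ω ≈ 179°, peptide C–N 1.33 Å);
the four turn-register offsets were solved so every turn residue falls in
a named favourable torsion region with no steric clash anywhere in the
stacked solenoid. An exact ideal-geometry backbone threading through
these sharp corners is over-constrained (the two-cone construction for
(φ, ψ) admits no solution along the turn for any branch choice), so the
turn backbone is placed by these fitted frame offsets instead; peptide
bonds at the two turn exits are consequently stretched by up to ~0.2 Å.
This is the one place the model trades local bond ideality for exact
C-alpha geometry; all C-alpha-level contracts (3.80 ± 0.05 Å spacing,
dimensions, ladder stacking, zero clashes) are exact.

Side chains default to C-beta only. The `idealized_rotamers` mode adds
full side chains with standard bond lengths in a fixed extended-χ
convention, oriented in a frame tied to the helix axis: hydroxyls and
small branches fan across the face, long inward chains (Gln, Glu, Leu,
Ile) climb the inter-coil gap so they do not pierce the opposite sheet,
and aromatic rings are tilted 45° from the axis so stacked ladder rings
clear each other. The mode supports ladder hydrogen-bond distance
checks; it is not a packing model, and the specific branch angles were
chosen once (by a clash-distance grid search over the consensus build)
and frozen.

Handedness: the right-handed build is the default; the left-handed build
is defined as its exact mirror image (x → −x). Either hand is plausible
for an ice-binding protein, and the mirror definition makes the
equivalence checkable to machine precision.

The residue numbering follows the input annotation, e.g. 217–345 for the
classic eight-coil segment. That span counts 129 residues although it is
conventionally described as a 128-residue segment; the package reports
both the residue count and the coil count (8 complete coils + 1 leftover
residue) and does not silently reconcile the discrepancy.

# Repeat detection

Detection scans all sixteen reading phases, scores each by total matched
non-wildcard consensus positions, and keeps the best (ties to the
smallest offset). Within the chosen phase the repeat array is the longest
run of windows whose first and last windows reach `min_identity`
(default 0.5); up to `max_bridge = 2` consecutive sub-threshold windows
are retained when flanked by qualifying ones. The bridge exists because
natural arrays are contiguous and contain occasional degenerate repeats:
with independent substitutions a strict per-window threshold will
eventually reject an interior window of a perfectly real array, breaking
it in two. Strict behaviour is available with `max_bridge = 0`. Identity
is computed over the ten non-wildcard consensus positions only, so a
wildcard never contributes to numerator or denominator. Terminal leftovers
shorter than 16 residues are reported with `partial = TRUE` and excluded
from every statistic.

# The synthetic-data generator

The generator defines the study conditions under which the hydration
pipeline is validated; it is not a tuning knob.

* **Sequences**: `n` tiled copies of the concrete consensus block
  `GYGSTQTAGEGSSLTA`, with i.i.d. substitutions at 15% per non-anchor
  position and 5% at the three ladder anchors (registers 2, 6, 12) —
  anchors are the most conserved positions of natural arrays (roughly
  90–98% identity), and 5% sits in the middle of that range. A
  per-position frequency profile can be planted instead (e.g. Thr present
  87%/92% of the time at the two exposed TxTA positions), which the
  frequency tables must recover within exact binomial confidence bounds.
* **Trajectories**: 100 frames (20 ps nominal spacing); every frame is
  the model under isotropic 0.3 Å Gaussian jitter per atom, each planted
  water present with per-frame Bernoulli occupancy 0.8 plus 0.25 Å
  jitter, and 2000 bulk waters drawn uniformly over the padded box with a
  2.4 Å hard core against protein and planted waters. Frame substreams
  are drawn once from the master seed, so earlier frames never change
  when the frame count grows. The deliberate simplifications — no
  correlated protein motion, no water–water structure, no hydrogen-bond
  kinetics — mean a passing pipeline demonstrates correct *signal
  processing* (alignment, accumulation, contouring, registration), not
  that real simulations would show the same ordering.
* **Planted nets**: the prism-plane oxygen net placed parallel to the
  TQTA or SLTA face at a 2.8 Å standoff, clipped to the face footprint
  (~44 sites on the eight-coil model).

# Hydration density

Waters within 10 Å of any protein atom deposit a normalized 3D Gaussian
of FWHM 1.0 Å on a 0.33 Å grid (Rcpp kernel; a pure-R per-voxel sum is
kept as the agreement oracle at 1e-9). The Gaussian kernel stands in for
the crystallographic route of computing structure factors and Fourier
inversion at 1 Å resolution; it is validated by planted-site recovery,
not by map-value identity. Map statistics (the σ scale) are computed over
the 10 Å shell mask by default rather than the whole box — computing them
over mostly-empty box volume would deflate the σ scale and make the
contour threshold depend on box padding; `sigma_domain = "box"` restores
the whole-cell convention. Sites are 26-neighbourhood local maxima at
σ ≥ 6, merged below 1.2 Å (just under half the 2.76 Å O–O distance,
keeping the higher peak), refined by per-axis parabolic interpolation,
and reported with the number of supporting frames. At the reference
sampling depth the planted peaks sit near 25–30 σ while the bulk
background stays below ~5.5 σ, so the 6 σ contour separates cleanly.

# Lattice registration

The ice Ih oxygen sublattice is the hexagonal-diamond arrangement (four
oxygens per cell, tetrahedral coordination; a = √(8/3)·d, c = (8/3)·d;
proton positions are irrelevant to spacings and omitted). Registration of
observed sites to a plane slice is iterative closest point: mutual
nearest-neighbour correspondence within 1.5 Å alternates with closed-form
Kabsch superposition to 1e-6 Å. The sites' best-fit plane is first
aligned with the net plane (both flips), then a deterministic multi-start
over 12 in-plane rotations × 9 sub-cell translations guards against
local minima. The best result is the one with the *most matched pairs*,
ties broken by lower RMSD — selecting on RMSD first would favour
degenerate small-subset fits and bias the reported RMSD below the value
implied by the site noise. Failure (fewer than 3 mutual pairs at
convergence) is reported as a non-converged result, not an error.

# Dimers and multimers

The parallel dimer duplicates the chain, rotates it 180° about the helix
axis, and translates it along the interface normal by a 1D root search
until the minimum tyrosine-ladder-to-opposite-chain heavy-atom distance
equals the requested gap (3.5 Å default, realized within 0.1 Å and
verified by exhaustive scan). The axial register of the two chains is
in-register (coil i against coil i); the data offer no constraint on a
one-coil stagger, so the simplest choice is the default. Hydrogen bonds
are counted with a heavy-atom proxy (donor–acceptor ≤ 3.5 Å, angle at the
donor ≥ 120°, each physical contact counted once); the as-built rigid
dimer has near-zero cross-chain hydrogen bonds because hydroxyl
orientations are not relaxed — interface hydrogen bonding is an emergent
property of simulation, which is out of scope, so the counting machinery
is validated on constructed geometries instead. Twist is measured (mean
signed rotation of the coil cross-section between successive coils about
the axis), never simulated. Offset multimers tile chains in two
alternating columns shifted by `offset_coils` per chain; one extra coil
of clearance is inserted whenever a chain starts past the end of the
previous chain in its own column, since abutting termini of rigid copies
would otherwise interpenetrate. The assembly length follows
`(n_coils + (n_chains − 1)·offset_coils) · rise`.

Two rises per coil coexist deliberately: the coordinate builder uses
4.8 Å (stacked β-sheet spacing), while area extrapolation from repeat
counts uses a nominal 5.0 Å so that 64 coils give a 320 Å face; both are
reported where relevant.

# Numerical choices and degenerate inputs

* Clash criterion: heavy-atom pairs below 2.5 Å, counted for residues at
  least two apart in a chain or on different chains (the adjacent-residue
  exclusion keeps legitimate 1-3 backbone contacts out of the list).
* Torsion classes are generous boxes: β (φ ∈ [−175°, −50°], ψ ≥ 60° or
  ψ ≤ −150°), its polyproline II sub-region, α (right- and left-handed
  boxes), otherwise "other"; glycine is additionally allowed anywhere.
  Geometry validation passes when there are no clashes and every
  strand-register residue classifies as β/PPII.
* Registration, peak merging and phase selection break ties
  deterministically (first index, lexicographic position), so identical
  inputs give bit-identical outputs.
* Degenerate inputs error early with the offending item named: empty
  sequences, non-standard residue letters, missing backbone atoms,
  zero-variance density maps, under-determined superpositions (< 3
  C-alphas), impossible multimer offsets.
* Maps are written as MRC2014 mode-2 volumes with the world origin in the
  header origin fields; the round trip is exact to float32 precision.

# Problem sizes

The test-suite and acceptance computations run at desk scale by design:
eight-coil models (128 residues, ~600–1900 atoms), 100-frame trajectories
with ~2000 bulk waters (~1.3 × 10⁵ shell observations on a ~3 × 10⁶ voxel
grid), 64-repeat sequence arrays, and 20 master seeds for the end-to-end
recovery study. These sizes give the planted signal the same statistical
structure as the reference protocol (100 coordinate sets, 10 Å shell)
while keeping any single stage under a few seconds.

# Limitations

* The builder produces one idealized conformation; it does not model the
  non-repetitive terminal domains, loop variability, or any relaxation.
* Turn-exit peptide geometry is mildly non-ideal (see above).
* The idealized side-chain mode is schematic; rotamer libraries and
  packing are out of scope.
* The hydration contract is defined against the synthetic water model;
  nothing here demonstrates that a physical water model would order the
  same way.
* Interface energetics (why the parallel dimer should be favoured over
  the anti-parallel one) are not computed; the package only provides the
  geometric measurables (flatness, twist, hydrogen-bond counts) that such
  an argument would use.
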