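---
title: "Pose-ensemble analysis of channel-pore docking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pose-ensemble analysis of channel-pore docking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porepose)
```

## The problem

Docking a drug into a homotetrameric potassium-channel pore produces a large
ensemble of scored placements. Channels like hERG (Kv11.1) are exactly
C4-symmetric, so four poses related by 90° rotations about the pore axis are
chemically the same binding mode; any clustering that works on raw
coordinates will split such modes into four. `porepose` implements an
analysis built around a symmetry-respecting pose descriptor, plus the
geometric bookkeeping that channel pharmacology cares about: occupancy of
the hydrophobic pockets behind the selectivity filter (implicated in current
facilitation), reach into the lateral fenestrations, and enclosure within
the pore when the intracellular gate closes (drug trapping).

## The pose descriptor and its metric

Each pose is summarised by a triple:

* `z` — ligand heavy-atom centre of mass projected on the pore axis,
  relative to the selectivity-filter (SF) Cα centre of mass (Å). Negative
  values lie below the SF, toward the cytoplasm.
* `l` — distance between the two *endpoint atoms* (Å).
* `phi` — polar angle of the oriented endpoint vector away from the +z axis,
  in [0°, 180°].

The pore frame is computed from the model itself: the origin is the SF Cα
centre of mass; the axis is the eigenvector of the SF Cα covariance whose
eigenvalue is most separated from the other two (the two in-plane
eigenvalues of a C4-symmetric point set are degenerate, so the distinct one
identifies the symmetry axis); the sign is fixed by requiring the
gate-residue centre of mass to project below the SF. The SF span is
configurable and defaults to residues 624–628 per chain, the standard
five-residue K-channel filter in hERG numbering.

Pose dissimilarity is the Euclidean distance between triples after range
normalisation of each component over the analysed ensemble (the selected
top-N, not any larger docking pool). Three choices here were genuinely open
and are worth recording:

* **The square root.** We use a proper Euclidean distance in the normalised
  space. The un-rooted sum of squares (available via `root = FALSE`) is a
  monotone transform, so cluster memberships under a cutoff are unchanged up
  to rescaling the cutoff; the rooted form makes the triangle inequality
  hold, which the test suite verifies on random triples.
* **Endpoint atoms.** "The two ends of the drug" is ambiguous for arbitrary
  chemistry. We define them as the maximal-distance heavy-atom pair of the
  reference (first) pose, with distance ties broken by the lexicographically
  smallest name pair, and we reuse those atom identities for every pose of
  the ensemble so `l` and `phi` remain comparable.
* **Orientation.** `phi` is measured on the oriented vector a→b in
  [0°, 180°], not folded to [0°, 90°]: with fixed endpoint identities, an
  inverted ligand orientation is a chemically different pose (cationic and
  neutral forms of the same drug are known to bind head-up versus
  head-down), and folding would conflate them.

A degenerate normalisation range (max == min, e.g. a perfectly rigid ligand
length) contributes zero rather than dividing by zero. One consequence of
range normalisation deserves emphasis: a component that carries *no*
between-cluster signal has its noise stretched to the full [0, 1] range,
inflating apparent distances. With real drugs all three components vary
meaningfully across binding modes; the synthetic defaults therefore also
separate clusters in every component.

## Two-stage clustering

Stage one is deterministic leader clustering on the dissimilarity matrix:
poses are visited in ascending interface-score order (ties by pose id), so
the best-scoring poses found clusters; a pose joins the first existing
cluster whose leader is within `cutoff`, else founds a new one; clusters
smaller than `min_size` become noise. Stage two refines the partition by
Lloyd's K-means on the normalised triples, with K fixed by stage one and
centers initialised at the lowest-interface-score member of each provisional
cluster. Noise poses do not steer the iterations and are assigned to the
nearest final center afterwards, so occupancy percentages are reported over
the full selected ensemble. Clusters are ranked by size, ties broken by the
lower representative interface score, and each cluster's representative is
its lowest-interface-score member — the pose used for interaction profiling.

**Defaults.** `min_size = 3` and `cutoff = 0.3`. The cutoff lives in the
normalised descriptor space, whose diameter is at most √3 ≈ 1.73. Measured
on tight synthetic ensembles (descriptor spreads of 0.25 Å in z, 0.15 Å in
l, 2.5° in phi — the convergence one sees in a well-behaved top-50 set),
intra-cluster pair distances reach ≈ 0.24 while distinct binding modes sit
more than 1.0 apart, so any cutoff in roughly [0.25, 1.0] recovers planted
partitions exactly; 0.3 sits at the conservative end. Because the upstream
value used with any particular deposited data set is unknowable,
`calibrate_cutoff()` sweeps the cutoff toward a target top-cluster size when
one needs to match a published cluster census. K-means uses
`max_iter = 100`, `tol = 1e-6` (maximum center shift); empty clusters retain
their previous center rather than being dropped, keeping K fixed as the
leader stage determined it.

## Regions and occupancy

Region definitions are geometric and deterministic, derived from the model:

* **Pocket anchors** — per chain, the centroid of the sidechain heavy atoms
  of the pocket residues (default T623, S624, V625, G648, Y652), with
  capture radius `r_pocket = 5.0` Å. A pose is "in the pocket" when at least
  one heavy atom falls within the radius of any anchor. This replaces a
  per-pose visual call with an auditable rule; the radius is configurable
  and can be calibrated against deposited pose sets.
* **Fenestration anchors** — per chain, the centroid of the fenestration
  residues (default M554, F557, A558, L622, T623, L646, S649, L650, A653),
  radius `r_fen = 5.5` Å. A pose is a fenestration pose when it reaches an
  anchor *and* its centre of mass lies radially outside the lumen bound
  R_lumen(z) interpolated from the pore profile — fenestration poses
  necessarily also overlap the lumen, hence the precedence below.
* **Axial bands** — `z_sf_base` is the minimum z of the SF Cα atoms;
  `z_gate` the mean z of the gate-residue Cα (default S660).
* **Category precedence** — fenestration > pore lumen > intracellular gate >
  membrane; a pocket-captured pose counts as pore lumen (the pockets extend
  up from the central cavity). Exactly one category per pose, so counts
  partition the ensemble.
* **Full enclosure** — every heavy atom inside the gate-to-SF axial band
  (extended by `r_slack = 2.0` Å) and within `d_enc = 6.0` Å of at least one
  protein atom. This is the trapping statistic for closed-state ensembles.
* **Pocket collapse** — the closed state has no pockets. The map flags
  pockets closed when every pocket anchor lies within `r_collapse = 2.5` Å
  of the protein-occluded part of the axis (slices whose pore radius falls
  below a 1.15 Å water probe); occupancy is still computed and is expected
  near zero.

Hydrogens are ignored throughout the region tests, since deposited poses may
or may not carry them.

## Pore-radius profile

A HOLE-style profile: for each slice of a 0.5 Å z-grid, the largest probe
sphere centred in the slice plane that avoids every atom's van der Waals
sphere (Bondi-type radii, carbon 1.70 Å, configurable), using full 3-D
distances so atoms above and below the plane constrain the probe. The
maximisation is a deterministic 3 × 3 multi-start grid around the axis
refined by Nelder–Mead — reproducibility was preferred over the simulated
annealing of the original tool, at the cost of assuming the pore is a
single, roughly axial channel (valid here; the search is local, so unrelated
cavities far off-axis are not reported). Radii cap at 15 Å with a flag.
Accuracy against analytic cylinders is better than 0.05 Å on interior
slices. Protein atoms only, by default.

## Interaction fingerprints

Simplified geometric criteria in the style of standard interaction
profilers, with all thresholds configurable: hydrophobic C···C ≤ 4.0 Å
(deduplicated per residue/ligand-atom pair), hydrogen bonds at
donor–acceptor ≤ 4.1 Å with a ≥ 100° donor angle when hydrogens exist, or a
heavy-atom-only 3.5 Å criterion (flagged `no-H`) when they do not; halogen
bonds ≤ 4.0 Å; π-stacking by ring-centroid distance (≤ 5.5 Å parallel,
≤ 7.5 Å perpendicular), normal angle and ≤ 2.0 Å in-plane offset; cation–π
≤ 6.0 Å; salt bridges between residue-level charge centres ≤ 5.5 Å. Protein
typing is atom-name based over the standard residues. Ligand typing comes
from a registry keyed by residue name: templates ship for the synthetic
test ligands, `register_ligand_template()` adds real drugs, and unknown
ligands fall back to element rules (O/N donors/acceptors, F/Cl/Br/I
halogens, carbons hydrophobic — no rings or formal charges are guessed).
Per-cluster "key residues" aggregate the representative's records by count
and chain multiplicity.

## The synthetic generator

`make_scaffold()` builds a C4-exact reduced channel: each landmark residue
is a Cα plus a pseudo-sidechain centroid atom — sufficient for every
geometric operation in scope while remaining tiny and fully controllable.
The open state has a 6.0 Å bore of carbon rings (hence a 4.30 Å pore radius
by closed form), pockets at 8.5 Å radius just below the SF base, and
fenestration sites at 9.0 Å. The closed state narrows the mid-pore to a
4.5 Å bore (2.8 Å pore radius in the drug-binding band), builds an
occluding 2.0 Å constriction at the gate wrapped in an outer bulk ring, and
collapses the pocket centroids toward the occluded axis; its SF breathes
radially outward by 0.4 Å so that open/closed SF comparisons have a known
non-zero answer. These constructions mirror the reported geometry of
open/closed channel-state models (pore radii ≈ 4.2–4.3 vs ≈ 2.8 Å; SF RMSD
0.4 Å between states).

`make_pose_ensemble()` draws descriptor triples from a planted cluster
mixture, realises each pose as a rigid rod at the sampled (z, phi) with a
uniformly random azimuth — so the descriptors' rotation invariance is
exercised end to end — places the centre of mass according to the cluster's
region tag, and draws interface scores with per-cluster offsets (default:
two clusters weighted 0.8/0.2, a dominant pocket cluster at −19 REU and a
smaller lumen cluster at −15 REU, i.e. a well-converged top-50 set). Ground
truth (labels, realised sizes, realised geometric pocket occupancy,
descriptors) is emitted alongside, and tests consume the truth output
rather than re-deriving it from generator internals.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: flexible ligand conformers (rods are rigid), docking
score landscapes (scores are Gaussian around cluster offsets), sidechain
rotamers and protonation, partial occupancy of several modes by one pose,
and the atom-naming vagaries of real PDB deposits. Recovery results on the
generator say the machinery is correct, not that any particular cutoff is
right for a given drug.

## Numerical choices and degenerate inputs

Determinism is enforced everywhere: lexicographic tie-breaks in selection,
endpoint choice and cluster visiting order; seeded generators; a fixed
multi-start pattern in the profiler. Degenerate cases degrade with warnings
rather than failures: single-chain models (C4 statistics unavailable),
unresolved residue-set members, poses without score rows, an all-noise
clustering (returned as such), fully capped profile bands (NA). Errors are
reserved for unusable input: fewer than 3 SF Cα landmarks, fewer than 2
heavy ligand atoms, mismatched residue spans in model comparison.

## Problem sizes

The test-suite and acceptance computations run at the scale the analysis is
designed for: 50-pose ensembles (top-50 selections), score tables up to
100,000 rows, scaffolds of ≈ 1,600–2,000 atoms with 0.5 Å profile grids,
and 200 seeded replicates (2–5 planted clusters, inter-center separation
at least 4× the intra-cluster spread) for recovery-rate estimation.

## Known limitations

* Pose selection and clustering trust the score table; no rescoring.
* The pore axis is assumed straight; curved permeation pathways would need
  a different profiler.
* Region membership is anchor-distance based, not surface based: a pose can
  be "in the pocket" through a wall in pathological geometries. The radii
  are conventions to be calibrated, not measured truths.
* Interaction typing without a ligand template is deliberately
  conservative; π and charge interactions require a registered template.
* Only one ensemble is analysed per call; cross-drug comparisons (whose
  interface energies are not comparable anyway) are left to the caller.
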