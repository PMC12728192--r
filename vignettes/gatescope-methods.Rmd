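---
title: "Lateral-gate analysis: models, parameters, and numerical choices"
author: "gatescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateral-gate analysis: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatescope)
```

## The scientific problem

Sam50 (mitochondria) and BamA (Gram-negative bacteria) are 16-stranded
β-barrels whose first and last strands meet at a *lateral gate*. Unlike
ordinary β-barrels the gate is dynamic: it must open for substrate β-barrel
precursors to fold, and β-signal mimics that bind strand β1 arrest the gate
in an open state and block biogenesis. Characterizing that gate
quantitatively requires a small set of structure-analysis computations —
rigid superposition and RMSD, a per-loop openness statistic, geometric
hydrogen-bond detection, membrane-thickness mapping, and ligand-pose
scoring. `gatescope` implements each of them with explicit, testable
conventions, plus a synthetic-data module that generates inputs whose
correct answers are known in closed form.

## Superposition and correspondences

Rigid superposition is the least-squares (Kabsch) fit: centroids are
removed, the 3×3 cross-covariance is decomposed by SVD, and the sign of the
smallest singular direction is flipped when needed so the result is always
a proper rotation (det +1; asserted to 1e-8 on every fit). Collinear point
sets produce a warning rather than an error — the transform is still a
valid minimizer, just not unique.

Correspondences between structures are explicit objects rather than an
implicit "same numbering" assumption. Three modes exist:

* `by_resid` — pair residues sharing `(res_seq, i_code)` in mapped chains;
  the right choice for conformers of the same protein.
* `by_alignment` — global Needleman–Wunsch on one-letter codes with match
  +1, mismatch −1, gap −2 and a fixed tie-break (diagonal first, then a gap
  in the second sequence), so the pairing is deterministic. Only aligned
  match/mismatch columns become pairs.
* `explicit` — a user table, used for cross-species loop pairings where
  slot identity must be exact and must not depend on an aligner
  (`inst/extdata/crossspecies_loop_pairs.csv` ships the gate-loop pairs).

Secondary-structure-matching superposition (as performed by interactive
model-building tools) is deliberately *not* re-implemented; correspondence
+ Kabsch replaces it. Published RMSD values obtained with SSM-style pairing
can differ from correspondence-based values at loop edges, which is why
comparisons against deposited models carry a ±0.15–0.2 Å tolerance in the
documentation of the fetch helper.

## The gate-openness statistic

Each gate loop is summarized by four marker residues chosen a few positions
inward from the loop tip (tips are mobile and weakly ordered; the inward
residues are reliably resolved). For a structure pair, the moving structure
is superposed on the reference over a fit core and the per-residue Cα–Cα
distances $d_i$ are measured. The loop average is the plain arithmetic mean
of the four $d_i$. Percent openness for a pair is

$$P = 100 \cdot \frac{\sum_i d_i(\text{pair})}{\sum_i d_i(\text{closed}
\leftrightarrow \text{stalled})}$$

with the closed↔stalled pair defining 100%. Two conventions matter:

* **Full-precision sums.** $P$ is computed from the raw distance sums,
  never from displayed means. With the bundled fixture, 56.56/73.95 =
  76.48% reproduces the printed cell while the ratio of the two-decimal
  displayed means (14.14/18.48) does not.
* **Truncated display.** Report tables *truncate* to two decimals
  (11.215 → 11.21, 4.9475 → 4.94); `display_trunc()` implements this with a
  1e-9 guard against binary representation fuzz. JSON output always carries
  full precision; truncation is display-only.

The superposition core for gate measurements defaults to *all* mutually
paired Cα atoms. For synthetic-oracle work the core should exclude the
mobile gate strands (the pipeline exposes `fit_strands`), because only a
fixed-core fit makes the displacement of a rigidly rotated gate atom equal
the chord length $2 r \sin(\theta/2)$ exactly — the identity the test suite
verifies to 1e-6.

## Hydrogen-bond detection

The criteria are the standard MD ones: donor–acceptor heavy-atom distance
≤ 3.5 Å and deviation from D–H⋯A linearity ≤ 30° (i.e. the angle at the
hydrogen is ≥ 150°). "Angle cutoff of 30°" is read as a bound on that
deviation. Donors and acceptors come from a bundled per-residue template
(backbone N donor except proline, backbone O/OXT acceptors, the usual polar
side chains); hetero-groups are annotated through user templates, and a
template for a 7-residue cyclized peptide ligand ships with the package.

Deposited cryo-EM and crystal structures lack hydrogens, so a heavy-atom
mode applies only the distance criterion plus a plausibility filter: the
donor–acceptor–antecedent angle (antecedent = the acceptor's covalently
bonded heavy atom, found by a < 1.8 Å same-residue search) must be ≥ 90°.
Counts from heavy-atom mode carry a ±1-bond ambiguity relative to
hydrogen-aware counts, which is documented wherever such counts are
compared. Covalent contacts are excluded by distance (< 1.8 Å) rather than
a connectivity table, because input files carry no reliable CONECT records;
intra-residue donor–acceptor pairs are always excluded.

Trajectory analysis (`seam_series`) counts bonds between the two seam
strands per frame and averages, optionally over only the last fraction of
frames, mirroring the common practice of analysing the equilibrated tail of
a production run.

## Membrane thickness

Headgroup particles are binned on an `nx × ny` lateral grid (default
45 × 45 over a 90 × 90 Å² window, matching the conventional analysis of a
bilayer patch around a membrane protein) with half-open cells
`[edge, next)`. Cell thickness is the mean upper-leaflet z minus the mean
lower-leaflet z within the cell — per-cell leaflet means, not
nearest-particle pairs, which is the simplest reading of a grid-based
headgroup-distance analysis; cells missing either leaflet are undefined.
Region means (global, or a 20 × 20 Å² patch near the gate) are computed
per leaflet with occupancy weighting, which makes the full-grid mean
*identical* to the gridless estimate (mean upper z − mean lower z) whenever
no particle falls outside the extent — a conservation identity the tests
assert to 1e-9. Particles outside the extent are dropped and counted.

## Map correlation and pose scoring

Simulated density places an isotropic 3-D Gaussian on every non-hydrogen
atom with σ = 0.225 × resolution (a common low-pass kernel convention;
external map tools do not publish their exact kernels, so σ is
configurable) and amplitude proportional to atomic number. Map–model CC is
the Pearson correlation between the experimental and simulated maps over a
mask formed by spheres of `mask_radius` (default 3 Å) around the scored
atoms; CC is invariant to affine intensity changes of the map by
construction, and a permutation-null test keeps |CC| < 0.05 on shuffled
voxels.

Interaction energy is a plain nonbonded sum over receptor–ligand pairs
within a 12 Å cutoff: 12-6 Lennard-Jones with Lorentz–Berthelot combination
plus Coulomb `332.06·q_i·q_j/(ε_r·r)` with ε_r = 80 (a solvent-mimicking
dielectric, as used in vacuum flexible-fitting protocols). There is no PME
and no switching function — plain truncation — because only *relative* pose
ranking is consumed downstream. The bundled parameter table is element-typed
and approximate (radii chosen so that β-sheet N⋯O ≈ 2.9 Å contacts sit near
the LJ minimum), with simple backbone partial charges; it is a ranking
device, not a force field, and users can supply their own table.

`rank_poses` scores each pose by CC (when a map is given), energy, and mean
interface hydrogen bonds, ranking primarily by CC, else by energy, with
deterministic tie-breaks (energy, then bonds, then pose id). The full score
table is always returned because the decision of interest may weigh the
best-energy pose against the most-hydrogen-bonded pose. Flexible-fitting
itself (density-biased MD) is out of scope; poses are scored as given.

## The synthetic generators

**Barrel.** `barrel_spec` records the standard sheared-barrel closed forms
— radius $R = \sqrt{(S a)^2 + (n b)^2}/(2\pi)$ and strand tilt
$\alpha = \arctan(S a / (n b))$ for $n$ strands, shear $S$, rise $a$ and
inter-strand spacing $b$ — with defaults $n = 16$, $S = 20$, $a = 3.3$ Å,
$b = 4.4$ Å (ten residues per strand). The generated *lattice*, however, is
deliberately untilted: strands are straight lines parallel to the barrel
axis, placed on a circle chosen so adjacent strand lines are exactly $b$
apart, with antiparallel residue numbering. This idealization trades
geometric realism (no shear-induced register spiral, no strand twist) for
exactness: every adjacent strand pair — including the β1–β16 seam — carries
an identical, analytically known hydrogen-bond register of four bonds at
even lattice levels, with N⋯O = 2.9 Å and ~14° deviation from linearity.
Consequences to keep in mind: openness percentages and chord-length oracles
are exact on these barrels, but absolute barrel radii and H-bond geometries
do not emulate a real sheared barrel, and passing tests on them demonstrates
correctness of the *analysis*, not realism of the *model*.

**Gate opening.** `open_gate` rigidly rotates strands 1..k (default 4)
about a hinge axis parallel to the barrel axis through the Cα line of the
first retained strand, by θ (default 45°, the outward rotation observed for
the open gate), in the sense that moves strand 1 away from strand 16. Every
rotated atom's displacement is exactly $2 r \sin(\theta/2)$ with $r$ its
distance to the hinge — the oracle used throughout the gate tests. θ = 0 is
the identity to machine precision.

**Bilayer.** Two leaflets of pseudo-headgroup particles at
$z = \pm t(x,y)/2$ plus Gaussian vertical noise (default sd 1 Å), with
$t(x,y) = 30 - d\,e^{-((x-c_x)^2+(y-c_y)^2)/2w^2}$: a 30 Å baseline (the
unperturbed membrane) and an optional local thinning. The default depth for
thinning studies is 17 Å, putting the imposed floor at 13 Å — the bottom of
the thinning range seen near lateral gates in simulation. The default 4000
particles per leaflet emulates a time-accumulated headgroup cloud (a single
bilayer snapshot has far fewer lipids); this density makes the 45 × 45 grid
well occupied, and the per-cell standard error implied by the noise is what
the recovery tests budget against. Lateral positions are uniform — no
lipid–lipid correlations, no protein excluded volume — so the generator
validates the grid statistics, not lipid physics.

**Seam trajectory.** A 5-state Markov chain on bond counts 0–4 (the zipped
seam's register is the cap) is sampled per frame; a frame in state $k$ is
realized *geometrically* by displacing the seam donor amides of the broken
bonds radially outward by 5 Å, so detection is exercised end-to-end rather
than against annotations. The stationary mean from the transition matrix's
eigenvector is the oracle; sample means are tested against the analytic
asymptotic standard error of a Markov-chain average.

**Pose set.** A 7-residue β-strand peptide mimic (W-N-W-S-K-S-F) is placed
along the exposed edge of the (opened) receptor's strand 1 in 4 in-plane
orientations × 2 end-group conformers = 8 poses labeled E1–E4/C1–C4.
Orientation 4 faces its amide donors at the receptor; the extended
conformer E4 forms the maximal backbone register (four bonds) and is the
planted ground truth for hydrogen-bond ranking, while the condensed
conformer C4 packs its terminal aromatic-ring mimic at van der Waals
contact with the receptor strand — gaining contact energy but occluding the
terminal amide (three bonds) — and is the planted interaction-energy winner.
This reproduces the structure of the real decision problem: the
most-hydrogen-bonded pose and the lowest-energy pose are different poses,
and the score table must expose both.

## Determinism and reproducibility

All generators take explicit seeds, save and restore the caller's RNG
state, and are bit-reproducible for a fixed spec. `run_pipeline` validates
its JSON config strictly (unknown keys are errors before any computation),
logs the seed and parameters, and produces byte-identical numeric outputs
for identical config + seed. Report-file truncation is applied only at the
display layer.

## Problem sizes used by the test and acceptance runs

The suite runs entirely on synthetic data: barrels of 16 × 10 residues
(800 backbone atoms), bilayers of 1500–8000 particles per leaflet,
trajectories of up to 2000 frames (with four replicas for the
stationary-mean check), and maps of ~2 × 10⁵ voxels. These sizes were
chosen so every oracle comparison is statistically meaningful while the
whole suite completes in about two minutes on a single core.

## Known limitations

* The PDB writer truncates serial/residue numbers modulo the fixed-column
  field widths; structures beyond 99,999 atoms per model should use mmCIF.
* Heavy-atom hydrogen-bond counts are a proxy; ±1 bond relative to
  hydrogen-aware counting.
* The energy table is for ranking; absolute kcal/mol values are not
  force-field quality.
* `by_alignment` uses linear (not affine) gap costs; for the short,
  high-identity chains it serves, this is equivalent to the affine case.
* The synthetic barrel does not emulate strand tilt, register spiral, or
  side chains; analyses validated on it still require sensible inputs on
  real structures (e.g. a user-chosen fit core that excludes the mobile
  gate).
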