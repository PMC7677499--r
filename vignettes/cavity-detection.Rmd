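---
title: "Grid-based cavity detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based cavity detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A cavity is defined operationally: a region surrounded by atoms that a water
molecule cannot enter when moving along a straight line from the outside.
This is a *static, directional* definition — it depends only on the
conformation and on which straight lines exist — and it is what makes the
measurement objective: no seed point, no visual identification, no surface
triangulation heuristics.

The implementation discretizes space into a cubic lattice of spacing $a$
inside a padded axis-aligned box. Atoms are hard spheres with per-element
van der Waals radii $r_i$ (shipped defaults: H 1.20, C 1.70, N 1.50, O 1.40,
S 1.85, P 1.90, other 1.80 Å; the exact per-element table is a config
artifact, overridable from a two-column text file, and its hash is recorded
in every survey row). Water is a probe sphere of radius $r_w$.

The pipeline per orientation:

1. **Rain.** From each of the six box walls, a probe center marches inward
   along every perpendicular grid line in steps of $a$, marking each visited
   point; the line halts permanently at the first position where the probe
   overlaps an atom sphere (strictly: center distance $< r_w + r_i$, so
   touching spheres do not block). Afterwards every point within $r_w$ of a
   visited point is marked as probe-covered exterior. Visited and covered
   points together delimit the outside.
2. **Classification.** Each remaining point is tested with the probe placed
   on it: overlap with any atom sphere means *material*, otherwise *cavity
   center*. Points within $r_w$ of a cavity center that are neither centers
   nor exterior become the cavity *halo* — they are swept by a probe sitting
   in the cavity and are counted into its volume, mirroring how the exterior
   covering is counted.
3. **Chambers.** Cavity centers are grouped into connected components under
   face (6-)adjacency; each halo point joins the chamber with the most
   center points within $r_w$ of it (ties to the lower label). The largest
   chamber (centers + halo) is *the* cavity; $V_C = a^3 \cdot$ its point
   count, $V_T = a^3 \cdot$ the material count, reported in nm³.
4. **Entrances.** A cavity point is an entrance when at least one of the six
   axis rays from it to the wall passes no grid point strictly inside an
   atom's van der Waals sphere — a straight, atom-free line connecting the
   cavity to the outside. Note the deliberate asymmetry with the rain: rain
   blocking inflates atoms by $r_w$, the entrance test uses bare atom
   spheres. Under the inflated test no cavity point could ever qualify (a
   probe-clear straight line would have been rained down), so entrances are
   exactly the lines a water *molecule center* cannot follow but a
   geometric sightline can — e.g. a bore narrower than a probe.

Six-directional, axis-aligned rain has an orientation bias; the algorithm
therefore repeats the whole procedure for $n$ uniformly random rotations of
the structure (quaternion sampling, applied about the centroid, box rebuilt
per rotation) and reports $V_C$ and $V_T$ as mean ± sd. All non-volume
quantities (surface, shell, descriptors) are computed on one *reference
orientation*: the rotation with the median $V_C$ (even counts: lower
median). The published protocol does not state how rotations are combined
for non-volume quantities; a median representative keeps every reported
number attached to one concrete, reproducible grid.

## Surface, closure fraction and the pocket criterion

The cavity surface is obtained by re-running the rain against a
pseudo-structure of probe-radius spheres centered on the chamber's cavity
centers: its reachable side separates the chamber from the outside, while
boundary faces toward holes enclosed inside the chamber blob are excluded.
The area is counted grid-natively — each exposed voxel face contributes
$a^2$ — which is exactly reproducible but overestimates smooth areas by a
bounded orientation factor (up to ~1.5 for a plane, ~1.9 for a sphere);
for this reason only the *ratio* $s = S_{CP}/S_C$ is compared against
published per-structure values, never raw areas. A surface point counts
toward the protein-contact area $S_{CP}$ when its nearest atom center lies
within $r_w + r_i + a$; the single lattice spacing absorbs grid
quantization of "immediate contact". A formation is a *pocket* when
$s < 0.21$, the threshold derived from the survey statistics
$\bar s - 3\sigma = 0.36 - 3 \times 0.05$; the inequality is strict and the
threshold is recomputable from any survey via `summarize_survey()`.

A geometric consequence worth knowing: under the straight-line definition
the cavity of an *open cup* is the shadow region behind the rim, which
always keeps a contact footprint on the wall. Opening the aperture first
erodes closure ($s$: 1.00 at 10° through ~0.73 at 120° for the shipped cup
fixture), but beyond that the remaining cavity degenerates into a thin
wall-hugging crescent whose surface is nearly all in contact, so $s$ turns
back *up* while $V_C \to 0$. Cup-like fixtures therefore never cross the
pocket threshold; real pockets that do are overhang-dominated shadows whose
mouth-side boundary dwarfs their contact footprint. The tests assert the
monotone regime (10°–120°) and the full-sweep volume decrease.

## Shell descriptors

The *shell* is the union, over all cavity-surface points, of the residue
containing the nearest atom (minimum center distance minus radius). Shell
membership is computed in the reference orientation's frame; the descriptor
geometry then uses the structure's input coordinates (membership is
frame-independent, and vector quantities stay in the user's frame).

- $H = \sum_i q_i$ over shell residues, $q_i$ the Kyte–Doolittle index,
  each residue once; non-standard residues are excluded with a recorded
  count.
- $\vec h = \sum_i q_i \vec\delta_i$, with $\vec\delta_i$ the residue center
  of mass relative to the mass-weighted center of mass of all shell-residue
  atoms. The summation runs over shell residues (the published summation
  bound is printed ambiguously; the shell reading is the only one consistent
  with the accompanying prose).
- $R_g$ is the RMS distance of shell-residue centers of mass from the shell
  center of mass, in Å. Residue position defaults to the mass-weighted atom
  centroid (a C$\alpha$ convention would differ negligibly for the shapes
  involved; the published choice is not stated). Published tables print
  $R_g$ under an "nm" header with magnitudes that are only consistent with
  Å; values here are Å throughout.
- The shape parameter uses the true moment-of-inertia tensor
  $I = \sum_k m_k (|\vec r_k|^2 \mathbb{1} - \vec r_k \vec r_k^{\,T})$ over
  all atoms of shell residues about the shell center of mass, eigenvalues
  $D_1 \le D_2 \le D_3$, radii $R_\alpha = \sqrt{D_\alpha / N_C}$ with $N_C$
  the shell *residue* count (the published normalization; dimensionally odd
  but kept as-is), and $w = (R_2 - \bar R)/\bar R$, $\bar R = (R_1+R_3)/2$.
  The moment-of-inertia convention (not the gyration tensor) is what makes
  cigars positive — for a thin rod $D_1 \approx 0$ so $R_2 \approx R_3$ and
  $w \to +1$ — and disks negative, with an oblate floor at
  $w = (1-\sqrt2)/(1+\sqrt2) \approx -0.17$ for ideal flat shapes.
  Collinear shells ($D_1/D_3 < 10^{-12}$) are rejected as degenerate.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `a` | 0.6 | Å | lattice constant; must stay below `r_w` so a marching probe cannot tunnel between steps. 0.6 trades ~2% volume error for survey-scale speed; 0.2–0.3 for precision work |
| `r_w` | 1.42 | Å | water-probe radius |
| `n_rotations` | 5 | — | orientations averaged; the sealed-sphere coefficient of variation is < 2% already at 1–5 |
| `seed` | 1 | — | drives all rotations; per-survey-entry seeds are derived as seed + stable hash of the entry id, so batches are order-independent |
| `padding` | max $r_i$ + 2$r_w$ + 3$a$ | Å | box margin guaranteeing rain, covering and halos never clip |
| `pocket_threshold` | 0.21 | — | $\bar s - 3\sigma$ of the survey statistics |
| `vt_includes_cavity` | FALSE | — | whether $V_T$ also counts cavity points (the published wording is ambiguous; material-only is the default reading) |

## The synthetic generators and what passing means

The fixture module builds valid PDB files whose cavity properties are known
in closed form, standing in for survey data in every test: a sealed
Fibonacci-lattice hollow sphere (expected $V_C = \frac43\pi(R_s - r_{atom})^3$,
$s \to 1$, $w \to 0$, $|\vec h| \to 0$, no entrances), open cups (aperture
sweep), a bored sphere (entrances without probe leakage, bore radius between
$r_{atom}$ and $r_w + r_{atom}$), dumbbells (chamber selection and
probe-dependent neck splitting), hydropathy-stamped shells (exact $H$ and
$\vec h$ sums, one atom per pseudo-residue so descriptors are exactly
controllable), and a ring of wedge chains that encloses space only as an
assembly. Atom spacing on every sealed shell is checked against the leak
bound $0.8 \cdot 2 r_w$ and generation fails loudly if violated. For the
*leaky* ring variant the wedges must be made narrow (~30°), not the gaps:
straight-line rain through slit-like gaps carves only thin columns and
leaves large shadow cavities, so slit gaps do *not* destroy the cavity.

These fixtures exercise every code path on geometry with analytic answers;
they do not emulate real proteins' rugged surfaces, side-chain packing,
partial occupancies or crystallographic artifacts. Passing them shows the
machinery implements the stated definitions correctly and converges on
smooth geometry — accuracy claims on real structures rest on the algorithm
definition itself, and spot checks against published per-structure values
require fetching those PDB entries.

## Numerical choices and degenerate inputs

- Overlap is strict (`<`), contact is non-strict (`<=`): touching spheres
  do not block rain, and a surface point exactly at the contact radius
  counts as contact.
- Rays stop permanently at first blockage; no re-entry deeper on the line.
- Chamber adjacency is 6-connected, preventing corner-touching voids from
  merging through gaps narrower than the probe. Surface *shells* of
  digitized blobs are 26-connected, not 6-connected — the connectivity test
  floods with the 26-neighborhood.
- Halo ties go to the larger chamber, then the lower label; `which.max`
  order makes largest-chamber ties resolve to the lower label too.
- Discreteness slack: on the sealed sphere the atom lattice (spacing
  ≤ 2.27 Å, triangle-hole circumradius ~1.3 Å) lets cavity centers sit up
  to ~0.35 Å beyond the continuum bound $R_s - r_{atom} - r_w$; analytic
  assertions carry exactly this slack.
- Empty structures, chainless selections, unparseable files, unknown
  elements (with defaults disabled), zero-surface chambers and collinear
  shells all fail with explicit messages; batch surveys record failures as
  rows and continue.
- Grids larger than `max_points` (3×10⁸) abort with advice to raise `a`.

## Problem sizes

Tests and the acceptance script run spheres of 200–900 atoms on grids up to
~150³ (lattice constants 1.2 down to 0.3 Å), 20 randomized blob fixtures on
≤ 40³ grids against a brute-force ray-casting oracle, and three-entry
surveys; the full suite completes in a few minutes on one core. Real
single-chain structures at $a = 0.6$, 5 rotations take on the order of
minutes each, dominated by the per-rotation grid passes.

## Known limitations

- Directional (6-ray) reachability is the *definition*, not an
  approximation of omnidirectional accessibility; rotation averaging
  reduces but does not remove the orientation dependence of a single run.
- Raw grid-face surface areas overestimate smooth areas by an
  orientation-dependent factor; compare ratios, not areas.
- No ensemble averaging over conformations: one structure, one (set of)
  answers.
- mmCIF input is out of scope; gzipped PDB is supported.
- The inertia-radius normalization $\sqrt{D_\alpha/N_C}$ follows the
  published formula; its absolute scale mixes mass and count units, so
  treat $R_\alpha$ (and hence comparisons of $\bar R$ across structures)
  as a shape diagnostic rather than a physical length.
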