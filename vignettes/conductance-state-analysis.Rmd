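---
title: "Conductance-state analysis of channel-gate trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductance-state analysis of channel-gate trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porestates)
```

`porestates` turns gate-region coordinates and reaction-coordinate
series into discrete conductance-state assignments.  This vignette is
the package's own account of the models it implements, the parameters
that matter, the numerical choices behind them, and what the synthetic
generators do and do not emulate.

## The coordinate frame

Every analysis runs in a gate-centred frame: the origin is the centre
of mass of the CA atoms of the reference residue (default 625, the
gate-exit threonine of an AMPA-receptor M3 helix, one atom per chain),
and the pore axis is the first principal axis of the gate-residue CA
atoms (614–625) of all four chains, mapped to z by the minimal
rotation.  The sign is fixed by the helix direction: the deeper gate
residues (lower residue numbers, toward the selectivity filter and the
cytoplasm) sit at negative z.  The principal-axis construction was an
open choice — no axis convention accompanies a centre-of-mass origin —
and was picked because it is symmetry-robust and needs no labelled
membrane normal.  The transform is rigid by construction (rotation
determinant +1), which the tests verify through distance-matrix
preservation.

## Gate features

Per frame the package computes: the χ1 dihedral of the gate threonine
(atoms N–Cα–Cβ–Oγ1, IUPAC sign), cross-tetramer CA distances at
residues 625 (A–C and B–D) and 617 (A–C), backbone RMSD of the gate
residues after optimal (Kabsch) superposition, the helix bend angle at
the hinge (angle between principal axes of the CA runs on either side
of residue 618, oriented by residue number, so a straight helix scores
0°), and the pore cross-section area at a marker residue (shoelace area
of the four CA atoms projected normal to the pore axis, vertices
ordered by azimuth).  Two definitions were genuinely open and are
declared rather than inherited: the residue anchoring the B–D distance
(we use 625, parallel to the A–C choice, configurable) and the pore
area measure (CA quadrilateral; no published definition exists).

Ligand-binding-domain (LBD) metrics follow the same pattern: the
clamshell closure angle α is measured as the rigid rotation of the
lower lobe (D2) after superposing the upper lobe (D1) onto a declared
apo reference — a declared substitute for an unpublished procedure —
together with the dimer separation d at residue 635 and the horizontal
and vertical D2 centre-of-mass positions L and H.  D1/D2 residue
partitions, dimer pairings and the apo reference are required
configuration, never guessed.

## Mixed angle/distance encoding

Angles live on a circle, distances on a line; a Euclidean embedding
needs both on one scale.  Each distance is standardised to unit
variance.  Each angle becomes a (sin, cos) pair multiplied by one
shared factor so the pair's total variance is 1.  The encoding is
invertible (atan2 recovers the angle) and periodic: 179° and −179° are
separated by the chord 2·sin(1°)·r, never by the arithmetic difference.
Constant features are dropped with a warning rather than silently
producing zero-variance columns.

## Pore radius and the conductance rule

The radius profile is the HOLE construction: at each z the radius of
the largest sphere centred in that plane touching no atom's van der
Waals surface.  HOLE's simulated annealing is replaced by a
deterministic search — coarse 1 Å grid over a ±5 Å lateral box, 0.1 Å
refinement, Nelder–Mead polish — so profiles are exactly reproducible;
on the analytic ring fixtures the result is within the 0.05 Å grid
tolerance.  vdW radii default to the Bondi set (the published analyses
do not name their set; the table is overridable).  Where a plane has no
confining atoms the radius is capped at 10 Å with a warning.  The gate
window defaults to the z-span of the 617–625 CA atoms and the
selectivity-filter window to the 586–590 backbone span; both are
configurable because the published figure windows are not printed.

R_min over the gate window maps to a state: **C** when R_min ≤ 1.4 Å
(water cannot pass), **O1** when 1.4 < R_min ≤ 2.3 Å, **O2** above
2.3 Å, boundaries inclusive on the lower state.

A note on inputs: profiling needs laterally closed walls.  The
marker-atom toy tetramer (four atoms per ring) is intentionally sparse
— built for analytic feature oracles — and lets the inscribed sphere
escape sideways; the dense-ring stand-in generator
(`gen_pore_standin()`, 16 atoms per ring) exists for radius work and
carries its true R_min as an attribute.

## Permeation counting

The counter is a two-plane hysteresis state machine expressed through
region collapse: each sample is above the entry plane (A), below the
exit plane (B), or between (M); dropping M samples leaves a sequence
whose A→B transitions are downward passages and B→A transitions upward
ones.  The published rule names the planes (−6 and −16 Å for water)
but not the re-entry behaviour; hysteresis is the standard
anti-double-count choice and is what makes the counter exact on
planted events — partial excursions between the planes collapse to
nothing, and passages that jump both planes within one stride still
register because regions, not plane landings, are compared.
Time-reversing a trace provably swaps the two counts.

Rates divide events by time, whole-trace or in 40 ns blocks spaced
200 ns (both defaults configurable).  Because fast recrossings are
better resolved at 10 ps than at 250 ps snapshot cadence, the package
reports an ordinary-least-squares recalibration of fine-stride on
coarse-stride counts — both with and without an intercept, since the
published functional form is not stated.  Ion counts under voltage V
convert to conductance G = n·q·e/(t·V) in pS.

Occupancy maps count species per (z, time) cell inside a lateral
cylinder (default radius 5 Å, matching the convention used to
visualise pore water) over −45 < z < 10 Å; a gate window is "open" in
a time bin when every z-cell inside it is occupied, and open intervals
are the maximal runs of open bins.

## Clustering

Coarse structure comes from k-means (k = 10 by default) on gate
backbone RMSD — on feature matrices this is `stats::kmeans`; on raw
coordinates the package runs Lloyd iterations under the per-pair
superposed-RMSD metric, since no installed package offers that metric.
Fine structure comes from the embedding chain: t-SNE to 2-D,
mean-shift with a small bandwidth, then a two-cutoff merge (clusters
merge when their centroids are within one cutoff *and* their closest
member points within another), applied transitively via union-find to
a fixed point, so the merge never increases the cluster count and is
idempotent.  Final labels are alphabetic by descending size (the
published labelling order is not stated).

Numerical choices, all configurable:

* **bandwidth** = 2 % of the embedding bounding-box diagonal;
  **centroid cutoff** = 4 × bandwidth; **point cutoff** = 1 ×
  bandwidth.  The published values are not printed; these defaults
  recover planted states reliably in the validation suite.
* **perplexity** defaults to 100.  With the exact-gradient t-SNE
  implemented here, small perplexities (30 and below) routinely
  fragment a single Gaussian state into several islands that no
  defensible merge cutoff reunites; 100 keeps each planted state one
  island while leaving distinct states separated.  It is reduced
  automatically when fewer than 3 × perplexity points are embedded.
* **iterations** default 300 (250 are used in the shipped validation
  runs); early exaggeration 12 for the first quarter.
* **landmarking**: above 2 000 frames the embedding runs on a seeded
  2 000-frame landmark subset and the remaining frames take the label
  of their nearest landmark in encoded feature space.  Exact t-SNE is
  quadratic in points; landmarking bounds the cost while leaving
  well-separated state structure intact.
* **orphan handling**: merged clusters holding under 2 % of embedded
  points (minimum 3) are stray embedding islets — typically a handful
  of isolated landmarks — and are dissolved into the nearest retained
  cluster.  The flip side is a reporting threshold: a conformational
  state must occupy at least 2 % of frames to appear as its own
  cluster.

Cluster angles are summarised by circular mean (atan2 of mean sine and
cosine) and circular SD √(−2 ln R̄) converted to degrees; distances by
ordinary mean ± SD.  The representative frame of a cluster minimises
the periodicity-aware Euclidean distance to the cluster mean, ties
breaking to the earliest frame.

## WHAM, errors and convergence

Umbrella windows (anchor, spring constant, samples) are unbiased by
iterating the self-consistent WHAM equations on a fixed grid
(bin width 0.1 Å, tolerance 1e−8 kcal/mol on the window constants,
10⁵-iteration cap — all unpublished, so declared here) at
kT = 0.596 kcal/mol (300 K).  The profile is −kT ln p anchored at
minimum 0.  Bins with fewer than 5 total samples are reported as
uncovered rather than as noise spikes.  Windows must overlap: adjacent
windows (by anchor) whose sample ranges leave more than one bin of
daylight raise a coverage-gap error naming the gap.

The autocorrelation time of a window is the smallest lag at which the
normalised autocorrelation falls to e⁻² (≈ 0.1353), 1 for white noise;
for an AR(1) process with coefficient φ the closed form is
⌈−2/ln φ⌉, which the tests check at φ = 0.8 (t = 9).  Bootstrap error
bars resample each window with replacement at the reduced size ⌊N/t⌋
and re-run WHAM per replicate; the per-bin SD across replicates is the
error bar.  Replicates (and the split-half convergence check, which
compares WHAM on first and second halves of every window) can be
anchored at the profile minimum or at the profile mean — the mean is
the right choice when comparing against a known flat truth, because
min-anchoring pins the noisiest bin to zero.

## The Langevin oracle

Umbrella inputs for validation come from overdamped Euler–Maruyama
dynamics with unit mobility: x' = x − dt·U'(x) + √(2 kT dt)·ξ.  Its
stationary law is Boltzmann in the small-step limit, with a known
O(κ·dt) variance inflation for quadratic wells — the validation runs
use dt = 0.002–0.005 so the bias stays inside the stated tolerances.
Stability requires dt·max|U″| < 2; a non-finite position aborts the
run.  The double-well form U = b((z/w)² − 1)² makes the barrier height
b an explicit parameter, so WHAM's recovered barrier has an exact
target (3 kcal/mol, recovered within ±0.3 at the default window
spacing 0.4 Å and spring constant 25 kcal mol⁻¹ Å⁻²).

## The synthetic generators, and what passing means

The generators emulate exactly the features the analyses consume: a
pseudo-4-fold marker-atom gate with per-subunit bends at the hinge and
exact χ1 placement (so every feature has an analytic target at zero
noise); 1-D z-traces with scheduled, recorded passages plus distractor
excursions that turn back between the planes (default distractor rate
equal to the crossing rate, exercising the rejection path); a
Markov-switching feature trajectory with wrapped angular noise; and
Boltzmann/Langevin samples from stated potentials.  Validation-scale
defaults: 5 000-frame trajectories for clustering (four states,
angular noise 15° against 120° separations — one sixth), 1 000-trace
permeation sets over 20 ns, nine 2×10⁵-step umbrella windows.  These
sizes keep the full suite within desktop minutes and are stated here
as the package's study conditions.

They deliberately do not emulate: force-field energetics, explicit
water geometry or membranes, correlated multi-ion motion, radial
structure in the traces (the counter only reads z, matching the
plane rule), or cryo-EM map noise.  Passing therefore demonstrates
that the analysis machinery is correct and calibrated on data with
known truth — not that any particular force field or deposited
structure is right.  Ground truth is always carried alongside the
generated data and never re-derived from it.

## State assignment

Per-cluster water permittivity (events/ns at zero voltage) is the
primary grouping metric because it exists for every equilibrium
cluster; ion conductance and PMF barriers corroborate.  Clusters are
grouped into at most four tiers by an exact 1-D minimum-within-variance
partition (the optimum 1-D k-means/Jenks seeks, computed by dynamic
programming), labelled C, O1, O2, O3 in order of increasing
permittivity.  A PMF barrier that grows with the state level is
flagged as inconsistent, never silently reordered.  O4 is reserved and
never assigned automatically: the conformation expected to reach it
(all four helices bent, wider backbone separation) was not captured at
conventional simulation lengths.  Boundaries between O-tiers are
data-driven by construction; no published quantitative boundaries
exist.

`run_pipeline()` chains everything on synthetic data — features,
clustering, timeline-attributed permeation events, state assignment —
writes TSV tables, a JSON and a markdown summary, and is byte-identical
under a fixed seed.  Permeation events are attributed to the cluster
active at the event's completion time, so no ground-truth labels leak
into the metrics.

## Known limitations

* Exact t-SNE means quadratic cost; landmarking is the scaling
  mechanism, and layouts (not cluster structure) vary across
  implementations.
* The pore profiler assumes an approximately axial pore; strongly
  tilted or branched channels would need an axis-following variant.
* LBD metric definitions (α, L, H) are declared substitutes for
  unpublished procedures; comparisons against published figures should
  use the definitions stated here.
* The deposited-structure worked examples require the PDB files on
  disk; the package ships only synthetic stand-ins with analytic
  ground truth.
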