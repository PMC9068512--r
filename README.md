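# porestates

Trajectory-analysis toolkit for assigning tetrameric ligand-gated
ion-channel gate conformations to discrete conductance states.

## The scientific problem

Single-channel recordings of AMPA-type glutamate receptors show a
baseline level C and up to four discrete conductance levels O1–O4.
Linking those electrical levels to gate structure requires a chain of
trajectory analyses: geometric description of the M3 gate (the
side-chain χ1 rotamer of the gate threonine T617, helix kinking at the
hinge alanine A618, cross-pore Cα distances at T617/T625), pore-radius
profiling of static structures, counting of water and ion passages
through the gate in simulation trajectories, unsupervised clustering of
gate conformations, and free-energy profiles for a permeant ion from
umbrella sampling.  `porestates` implements that chain as reusable,
tested R functions, together with synthetic-data generators that plant
known ground truth so every stage can be validated end to end without a
molecular-dynamics engine.

Who it is for: structural biologists and simulators who have gate-region
coordinates (PDB/mmCIF, multi-model PDB trajectories) or reaction-
coordinate series and want reproducible conductance-state analysis.

## The core methods

* **Pore radius and conductance class.**  At each axial position z the
  pore radius is the largest sphere centred in that plane that touches
  no atom's van der Waals surface (the HOLE construction), found here by
  a deterministic grid + Nelder–Mead search.  The minimum radius over
  the gate window, R_min, classifies the structure: C when
  R_min ≤ 1.4 Å (the radius of water), O1 when 1.4 < R_min ≤ 2.3 Å,
  O2 when R_min > 2.3 Å.
* **Permeation counting.**  A particle completes a downward passage when,
  after crossing the entry plane (Z = −6 Å), it reaches the exit plane
  (Z = −16 Å) before re-crossing the entry plane backward — a two-plane
  hysteresis that cannot double-count partial excursions.  Ion counts
  under an applied voltage V convert to conductance as
  G = n·q·e / (t·V) in pS.
* **Conformational clustering.**  Angles enter as (sin, cos) pairs scaled
  to unit total variance so angles and distances carry equal weight;
  t-SNE embeds the per-frame feature vectors; mean-shift with an
  intentionally small bandwidth seeds clusters; clusters merge when both
  their centroids and their closest points fall inside two cutoffs;
  cluster angles are summarised by circular mean and circular SD
  √(−2 ln R̄).
* **PMF estimation.**  Umbrella windows (0.4 Å spacing, spring constant
  25 kcal mol⁻¹ Å⁻² by default) are unbiased with WHAM
  (F = −kT ln p, minimum anchored at 0).  Error bars come from a Monte
  Carlo bootstrap that resamples ⌊N/t⌋ points per window, where t is the
  lag at which the autocorrelation falls to e⁻²; convergence is checked
  by comparing PMFs from the two halves of every window.

## Worked example

```r
library(porestates)

## A stand-in channel with a known 1.8 A gate constriction
m <- gen_pore_standin(1.8)
p <- pore_radius_profile(m, z_range = c(-12, 0), step = 0.25)
p
#> pore_profile: 49 z-points in [-12.0, 0.0] A
#>   rmin (gate window -12.0..0.0 A): 1.80 A -> O1
classify_conductance(p$rmin_gate)
#> [1] "O1"

## Count planted water passages
tr <- gen_particle_traces(1000, rate_down = 2, rate_up = 0.8,
                          duration = 20, stride = 20, seed = 1)
lg <- count_crossings(tr)
lg
#> crossing_ledger: 36 down, 21 up over 20.0 ns (planes -6 / -16 A)
c(counted = lg$n_down, planted = tr$planted_downward)
#> counted planted
#>      36      36

## Ion counts to conductance: 15 events, 360 ns, 600 mV
conductance_from_counts(15, total_time_ns = 360, voltage_mV = 600)
#> [1] 11.12623      # i.e. ~11.1 pS
```

The pore profile prints the minimum gate radius and its conductance
class; the ledger shows that the hysteresis counter reproduces the
planted event counts exactly; the conductance line is the elementary
charge arithmetic used to convert simulated ion counts.

## Selection mini-language

Atom selections are expressed as conjunctions of vector-valued
arguments to `select_atoms()`, e.g.
`select_atoms(model, chain = c("A","C"), resno = 614:625,
elety = c("C","O","N","CA","CB"))`.
A `NULL` argument places no constraint; an empty result is an error,
never a silent empty set.

## Limitations

* Pore profiling needs laterally closed walls; sparse marker-atom toy
  models are for feature oracles, not radius profiles.
* The deposited cryo-EM structures referenced in the tests' stand-in
  fixtures are not shipped; with the PDB files on disk the same calls
  (`read_structure()` → `align_to_gate_origin()` →
  `pore_radius_profile()`) reproduce the published C/O1/O2 assignment.
* t-SNE layouts are not comparable across implementations; only the
  cluster structure is contractual.
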