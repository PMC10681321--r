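---
title: "Mechano-regulated sprouting angiogenesis in early bone healing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-regulated sprouting angiogenesis in early bone healing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem

During the first week after a stabilized long-bone osteotomy, the healing
region — the cut cortices, the marrow cavity, the granulation-filled gap
and the soft periosteal callus — must be revascularized. Sprouting
angiogenesis in this window is shaped by two mechanical signal classes:
the macroscopic strains imposed by the fixation device and physiological
loading, and the microscopic deformations that endothelial cells (ECs)
and outer-vascular stromal cells (OVSCs: fibroblasts, pericytes,
mesenchymal stromal cells) themselves generate by pulling on the matrix.
`sproutmech` simulates both cell populations on a regular lattice coupled
to a plane-strain finite-element model of the healing region, so that the
two signal classes can be switched on and off independently (fixation
presets, an unloading scenario, a tip-cell mechano-response knockout and a
stromal traction-force knockout).

## Model overview

One iteration represents 20 minutes of healing; a standard run covers 7
days (504 iterations). Each iteration executes a fixed loop:

1. every active tip EC and every stromal cell is converted into a
   contractile force dipole (two opposed point loads on the lattice nodes
   adjacent to the cell along its axis; 20 µN total for tip ECs, 32 µN
   for OVSCs, 0 N under the traction knockout);
2. the plane-strain linear-elastic problem is solved for the current
   loads and boundary conditions;
3. the element strain field is reduced to the absolute maximum principal
   strain `EP` (the principal component of largest magnitude, sign
   retained, compression negative) and its direction `θ ∈ [0°, 180°)`,
   with 90° the bone long axis;
4. endothelial updates: direction choice, elongation, branching,
   anastomosis, the periodic out-of-plane exchange and the callus-front
   ingrowth;
5. stromal updates: migration, orientation re-evaluation, proliferation
   and apoptosis.

### Tissue-scale mechanics

The mid-longitudinal section is meshed with square 4-node plane-strain
elements whose node spacing (0.01 mm) equals the cell lattice pitch, so
finite-element nodes double as lattice positions. Tissues are linear
elastic: granulation 0.2 MPa, marrow 2 MPa, cortical bone 5000 MPa
(Poisson 0.167/0.167/0.3). Geometry and materials never change within a
run, so the constrained stiffness operator is factorized once and each
iteration costs a single back-substitution.

Fixator loading is a surrogate: the exact displacement histories of the
cortices under gait are not available to the package, so the `rigid` and
`semirigid` presets apply a uniform axial closing displacement to the
cortical fragments (with a 1.2 medial:lateral linear asymmetry standing
in for the bending component) whose amplitude is calibrated — exactly,
by linearity, in a single unit solve — so that the mean compressive gap
strain matches the preset's interfragmentary strain (11% rigid, 45%
semirigid). `unloaded` fixes every cortical node in all degrees of
freedom and leaves only cell-generated forces.

### Endothelial rules

Microvessels are ordered sequences of ECs on the lattice with one leading
tip. Per migration attempt a tip draws one of three rules: persistence
(probability `p1 = 0.4`), a uniform random lattice direction
(`p2 = 0.4`), or the strain rule (`p3 = 0.2`): migrate along `θ` while
`|EP| ≤ 5%`, perpendicular to it for `|EP| ≥ 10%`, linearly interpolated
in between, and do not migrate at all above 30%. Elongation uses an
accumulator: 15 µm/h credits 5 µm per iteration, a straight step costs
10 µm and a diagonal step 14.14 µm. Touching another vessel (or the own
path — counted as a self-loop) is anastomosis: the cell loses its tip
phenotype and the sprout stops. Branching is stochastic with probability
proportional to vessel length; every 15 iterations tips that last moved
randomly leave the plane with probability 10/17 and an equal number of
new tips enters at sparsely vascularized granulation points; the virtual
callus circumference shrinks at the growth rate and seeds new ECs behind
it (probability 0.5% where local vessel density is below 10%).

The initial vasculature comprises 10% of the *periosteum* — read as the
thin (30 µm) vascularized membrane on the outer cortex surface, not the
whole callus, because the model's own front-ingrowth design presumes an
initially avascular callus — 1% of marrow points, and the callus
circumference itself, seeded as connected arcs representing the
surrounding vasculature (seeding it as hundreds of adjacent single-cell
sprouts would instantly fuse them into zero-length fragments and distort
every length statistic).

### Stromal rules

OVSCs occupy 20% of marrow and periosteal-callus points at the start,
with one of four dipole orientations (0°, 45°, 90°, 135°). For the first
4 days they perform a density-biased random walk (one 10 µm step per 8 h,
matching 30 µm/day; candidate weights `1 − local occupancy`), emulating
growth-factor attraction toward the sparse gap. From day 4, durotaxis:
a trial configuration (random free neighbour plus random orientation) is
adopted only if its probed deformation is strictly lower.

The probed deformation has two terms, both on a strain scale:

* **compliance probing** — the relative approach of the cell's two
  dipole-loaded nodes under its own traction. Solving this on the global
  mesh for every trial is prohibitively expensive, so it is solved on a
  clamped 5-element-radius patch around the cell and cached by the local
  material pattern; the patch truncates only ~3–6% of the full-solve
  response (a dipole's field decays with the inverse square of distance)
  and a one-off exact/patch calibration at the domain centre removes the
  residual. Each orientation is normalized by its homogeneous-granulation
  reference so that straight and diagonal dipole arms (which differ in
  length by √2) probe commensurable quantities: in uniform unloaded
  tissue no orientation is preferred, and stiffer surroundings always
  probe less — the classical durotaxis drift.
* **strain response** — the local environmental strain tensor (mean of
  the node's incident elements, the probing cell's own patch-solved
  contribution subtracted so a cell does not mistake its own traction
  for environment) defines a preferred axis with the same thresholds as
  the endothelial rule: along `θ` of `EP` below 5%, perpendicular above
  10%, ramped between. Angular distance from that axis is penalized in
  proportion to `|EP|`. This unified EC/OVSC strain response was a
  deliberate modelling choice: a raw "axial approach of the pole nodes"
  metric was implemented first and measurably fails in collectives —
  sparse neighbours act as radial contraction centres, which aligns cells
  with the population band rather than with the anchored tension mode,
  contradicting the reported orientation outcomes under both loading and
  unloading.

Orientation is re-evaluated in place every iteration (cells probe
continuously), while position changes remain limited by the migration
rate. Only a random third of cells re-evaluates per iteration: full
synchronous updating — every cell responding to the previous iteration's
field at once — was observed to freeze seed-dependent chiral diagonal
domains, a known artifact of synchronous best-response dynamics; updating
a random subset removes it, and a much smaller fraction (one tenth)
under-converges within the 3-day durotaxis window.

Proliferation (33%/day) places daughters on free neighbours (contact
inhibition), apoptosis removes 0.03%/day; both are Bernoulli per
iteration.

### Occupancy

ECs and OVSCs live on separate occupancy layers by default: the two
populations of a thick histological section project onto one plane, and
only vessel–vessel contact is anastomosis. A `shared_occupancy` switch
makes the types mutually exclusive instead.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `pitch` | 0.01 | mm | lattice/mesh spacing = cell diameter |
| `gap_width` | 0.7 | mm | osteotomy gap |
| granulation / marrow / cortex E | 0.2 / 2 / 5000 | MPa | tissue stiffness |
| `p1, p2, p3` | 0.4, 0.4, 0.2 | – | tip migration mix (knockout: 0.4, 0.6, 0) |
| strain thresholds | 5, 10, 30 | % | parallel / perpendicular / halt |
| `growth_rate_um_h` | 15 | µm/h | vessel elongation |
| `ec_force_total`, `ovsc_force_total` | 20, 32 | µN | dipole magnitudes |
| `branch_coeff` | 1e-5 | per µm per iteration | branching density |
| `oop_prob`, `oop_period` | 10/17, 15 | –, iterations | out-of-plane exchange |
| `ingrowth_prob`, cap | 0.5%, 10% | – | front vascularization |
| `seed_frac` (OVSC) | 20% | – | initial stromal occupancy |
| `migration_rate_um_day` | 30 | µm/day | stromal step cadence |
| `proliferation_day`, `apoptosis_day` | 0.33, 0.0003 | fraction/day | stromal turnover |
| `durotaxis_onset_day` | 4 | days | switch from density walk |
| `relax_fraction` | 1/3 | – | per-iteration orientation updates |

`branch_coeff` deserves a note: it is inherited conceptually from earlier
vascular lattice models and is not pinned by measurement. At 1e-4 the
network runs away (thousands of sprouts, vessel length density ratios of
0.3–0.5 in every region — far denser than any early-healing histology);
the default 1e-5 produces density ratios around 0.1–0.2 and is exposed in
the configuration and in the sweep harness for sensitivity analysis.

## Study sizes and the synthetic-data scope

The packaged study geometry (`study_domain()`) keeps every cell-scale
quantity at full fidelity — 0.01 mm pitch, the complete bone
cross-section (1.0 mm marrow, 0.2 mm cortices) and the full 0.7 mm gap —
and scales down only the surrounding callus: a complete 0.9 mm-radius
circle inside 1.9 × 1.9 mm (the full-size geometry is a 2 mm-radius
callus in roughly 4 × 5 mm). Scaling the callus, not the bone, matters:
an earlier desk geometry that thinned the marrow to 0.5 mm moved the
flanking contractile cell masses close enough to the gap core to reverse
the unloaded stromal orientation outcome. The remaining known truncation
effect is conservative in the same direction: with a smaller callus the
flanking masses sit relatively closer than at full size, which dilutes
(never inflates) the axial alignment signal in the unloaded gap.

Simulated networks emulate: seeded vascular sources, invasion fronts,
strain-guided growth, fusion, branching, self-loops, and stromal
self-organisation. They do not emulate: chemotactic growth-factor
fields, oxygen transport, ECM fibre deposition and contact guidance,
viscoelasticity, or mechanics-dependent growth rates — so quantitative
agreement on patterning metrics supports the mechanical hypotheses but
does not validate the model against biochemically dominated situations.

## Numerical choices

* Plane strain, unit out-of-plane thickness; mm/N/MPa units.
* 2×2 Gauss quadrature on identical square elements: one 8×8 element
  matrix per material, sparse scatter assembly, cached sparse Cholesky;
  each iteration is one back-substitution (relative residuals are at
  machine level because the factorization is direct).
* Principal decomposition by the closed 2×2 form; when both principal
  magnitudes tie, the compressive one is reported, and a zero tensor
  reports 90° (the dominant loading mode's axis).
* Element strains are sampled to lattice nodes by averaging the incident
  elements' tensors (tensors, not angles) and decomposing the average.
* Continuous target angles map to the nearest of the 8 lattice
  directions; the forward sense maximizes the dot product with the
  previous step (no immediate reversal); exact ties are broken by the
  RNG, as is the side of the parallel-to-perpendicular ramp.
* All randomness flows through R's RNG; a run is a pure function of
  (configuration, seed). Checkpoints capture the full state including
  the RNG stream and resume bit-identically.
* Movie export writes per-iteration PNG frames at lattice resolution;
  assembling them into an animation is left to external tools.

## Known limitations

* The fixator displacement boundary conditions are calibrated surrogates,
  not recordings; intracortical strain gradients therefore only
  approximate the real fixator's.
* Point-load dipoles create strain spikes in the elements adjacent to
  their poles; the maximum over elements of the cell-induced field is
  dominated by these spikes rather than by tissue-scale strain.
* The durotaxis potential is a model: its strain-response term encodes
  the same thresholds as the endothelial rule rather than an independent
  stromal dose–response, because no quantitative stromal re-orientation
  curve was available.
* 2D: out-of-plane vessel behaviour is captured only by the statistical
  exchange rule; stromal cells have no out-of-plane pathway at all.

## Reproducing the study numbers

`scripts/acceptance.R` (repository root) regenerates the headline
quantities from scratch — the unloaded, rigid-baseline and
mechano-response-knockout scenario sets, six replicates each, plus the
deterministic tip-speed experiment — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
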