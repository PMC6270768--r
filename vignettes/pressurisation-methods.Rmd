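---
title: "Grid-based active site pressurisation: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based active site pressurisation: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pocketcast)
```

## The method

Active site pressurisation grows a *cast* of soft particles inside a
binding pocket to map where the pocket can yield. A cubic lattice
(spacing 1.1 Å) of candidate particles is centred on the site; particles
are in one of three states. *Inactive* particles do not interact at all.
*Latent* particles — the lattice neighbours of the cast — are held fixed
and act as one-way probes: at every integration step the net
Lennard-Jones force each latent site would experience from the protein
(and, optionally, from the active particles) is evaluated and its
magnitude accumulated. *Active* particles are ordinary dynamical
particles, tethered to their lattice sites by weak harmonic anchors.
After each activation interval the latent particle with the smallest
time-averaged force magnitude is activated and its inactive lattice
neighbours become latent. Exact ties resolve to the lowest linear
lattice index, which makes runs reproducible bit-for-bit for a given
seed.

Because the particle–particle equilibrium distance (1.4 Å) exceeds the
lattice spacing (1.1 Å), a filled region of cast is intrinsically
compressed and pushes outward on its surroundings: the cast
*pressurises* the pocket, and growth proceeds along whichever directions
the protein resists least.

## Force model and units

Internal units are Å, kcal/mol, Da and ps (1 kcal mol⁻¹ Å⁻¹ Da⁻¹ =
418.4 Å ps⁻²).

* **Particle–particle**: 12-6 Lennard-Jones in r_min form,
  E(r) = ε[(r_min/r)¹² − 2(r_min/r)⁶], ε = 0.1 kcal/mol, r_min = 1.4 Å.
* **Particle–protein**: protein atoms are soft LJ spheres with a single
  size parameter (`rmin_protein`, default 3.0 Å) combined with the
  particle r_min by arithmetic mean (2.2 Å). A `protein_wca` switch
  truncates and shifts this interaction at its minimum (WCA), keeping
  only the repulsive branch; see *Validation* for why that matters.
* **Protein–protein**: an elastic network — one harmonic spring per atom
  pair closer than the cutoff, rest length equal to the build-time
  distance. This is a deliberately coarse stand-in for a full force
  field: it preserves the local stiffness structure of the protein,
  which is the property pressurisation probes, and nothing else.
* **Soft core**: below `core_frac` × r_min (default 0.6) the pair
  potential continues linearly with the boundary force. A freshly
  activated lattice particle that overlaps existing matter then pushes
  with a large but finite force (hundreds of kcal/mol/Å) instead of the
  divergent 12-6 wall, which would otherwise inject unbounded kinetic
  energy at a 1 fs step. The pure 12-6 form is unaffected at
  r ≥ 0.6 r_min, where all analytic contracts are tested.
* **Electrostatics**: none anywhere — the particles are uncharged by
  construction and the protein stand-in is likewise uncharged.

## Integrator and protocol

Dynamics are velocity Verlet with a BAOAB-split Langevin thermostat
(collision frequency 1 ps⁻¹ by default; `thermostat = "none"` gives NVE
for conservation tests). The standard protocol is: a heating ramp from
0 K to the target temperature (default 300 K) over `ramp_time`
(default 115 ps) during which protein positional restraints are released
linearly from 100 kcal/mol/Å² to zero; then pressurisation at constant
temperature with one activation per `activation_interval` (default
1 ps) over `duration` (default 400 ps) at a 1 fs step, saving
coordinates once per interval. Latent and inactive particles never
move; active particles are restrained to their lattice anchors at
0.1 kcal/mol/Å².

Latent probes are one-way: they feel forces but exert none, so the
dynamical system (protein + active particles) obeys Newton's third law
exactly — `total_forces()` checks this — while accumulation remains a
pure measurement. An interacting fixed latent shell would wall off the
pocket and suppress the very distension the method measures, which is
why the probe reading was chosen.

## Analyses

* `atomic_fluctuations()` — per-atom RMSF about the mean after optional
  Kabsch superposition of every frame (fit to frame 1, re-fit to the
  resulting mean).
* `rmsd_series()` — per-frame fitted RMSD against any number of named
  references in one pass (initial conformation, later snapshots,
  crystal structures).
* `com_distance_series()` / `histogram_probability()` — mass-weighted
  (default) or geometric centre-of-mass distances between two residues,
  and their probability distribution.
* `segment_stages()` — exact dynamic-programming piecewise-linear fit of
  the (particle count, RMSD) curve. Pressurisation runs typically show
  four stages — cavity filling, side-chain rearrangement, expansion into
  free volume, late protein distension — and the DP fit makes the stage
  boundaries reproducible instead of narrative. The residual is
  non-increasing in the number of segments by construction.
* `latent_force_map()` / `cast_shape()` / `cast_extent()` /
  `cast_principal_axis()` — the force-coloured latent shell at any
  event, and gyration-tensor descriptors (λ₁ ≥ λ₂ ≥ λ₃, asphericity
  λ₁ − (λ₂+λ₃)/2, elongation λ₁/λ₃) of the activated sites. Shape
  descriptors default to the lattice anchor positions of activated
  sites rather than instantaneous coordinates: at 300 K the thermal
  positional spread of a particle in a 0.1 kcal/mol/Å² anchor is
  ~2.4 Å, which would blur the geometry the cast records; the
  instantaneous mode remains available.
* `fit_pca()` — covariance PCA of the masked, superposed coordinates
  (SVD of the centred frame matrix). Backbone masks are N, Cα, C per
  residue (O optional), mass-unweighted. `overlap_matrix()` compares two
  eigen-systems by absolute inner products; it requires the same mask
  dimension and bitwise-equal fit reference, because eigenvectors from
  differently-fitted trajectories are not comparable. Eigenvector signs
  are arbitrary, hence absolute values. `detect_drift_mode()` flags the
  mode whose projection correlates with time above a threshold (default
  |r| ≥ 0.9) — the signature of pressurisation-driven deformation as
  opposed to thermal oscillation, replacing visual inspection of
  projection plots with a statistic; constant projections are treated
  as non-drifting.

## Synthetic fixtures and what the validation shows

`make_kinase_like_fixture()` builds a 278-residue single-chain backbone
(residues 7–284) whose residue identities at the nine core-range
endpoints are correct, so parsing the printed ranges, validating their
one-letter codes and extracting the 642-atom core mask are exercised end
to end. The geometry is a loose helix — adequate for bookkeeping,
superposition and PCA plumbing, deliberately not a kinase fold.

`make_toy_pocket()` builds the pressurisation test bed: a thick
spherical shell (two staggered bead layers 1.5 Å apart, default 260
beads, cavity radius 4.4 Å, empty interior) connected as an elastic
network. Springs whose bond segment crosses a cylinder of radius
0.75 × cavity radius around `soft_axis` are scaled by
`stiffness_ratio`, turning the two polar caps into compliant lids;
`stiffness_ratio = 1` gives an isotropic pocket. Two layers matter: a
single bead layer can be crossed through one lattice gap at moderate
cost, and the cast then leaks through random wall defects instead of
following the soft axis.

The soft-axis validation study (10 seeds, 150 activations each) runs
with `stiffness_ratio = 0.05`, a 9.9 Å box, a 0.25 ps activation
interval, a 2 ps ramp, `protein_wca = TRUE` and
`latent_feel_active = FALSE`. These choices isolate the signal the
study is about:

* **WCA walls.** With the full 12-6 particle–protein interaction the
  wall beads sit in the attractive well of the growing cast: the shell
  creeps inward and the zero-force ring at bead-contact distance
  becomes the cheapest region of the whole lattice, so the cast coats
  the wall isotropically. Repulsion-only walls restore the intended
  monotone relationship between wall clearance and probe force.
* **Protein-only probes.** With probes also feeling the active
  particles, the frontier ordering is dominated by how far each site's
  single cast neighbour happens to wander from its anchor — a noise
  term that makes free-space growth dendritic. Probing the protein
  force alone leaves a smooth distance-to-wall gradient, and the cast
  fills the cavity shell by shell, elongating along the axis where the
  lids yield. Both probe modes are implemented (`latent_feel_active`),
  and the default for production runs remains on.

Under those conditions the cast's principal gyration axis aligns with
the planted soft axis (|cos| > 0.8) in 9 of 10 seeds, and the cast
extent along the soft axis exceeds both perpendicular extents in 10 of
10 — the package's end-to-end demonstration that pressurisation finds
compliant directions. Note what this does and does not show: the
fixture has a single, geometrically clean compliance axis and no
side-chains, solvent, charge or tertiary rearrangement; passing it
validates the machinery, not the biology of any particular pocket.

`make_planted_trajectory()` plants orthonormal harmonic and drift modes
(with rigid-body components projected out, so superposition does not
mix them) plus white noise. PCA recovers a 4:2:1 amplitude triple at
2000 frames with overlaps > 0.95, and the drift detector finds a ramp
buried in 10 %-of-range noise in ≥ 95 of 100 seeds.

## Numerical choices and degenerate inputs

* Time step 1 fs (default); the stiffest default interaction
  (particle–particle LJ) has a vibrational period of ~0.36 ps, ~360
  steps per period. NVE drift of an LJ dimer is < 10⁻⁷ kcal/mol over
  10⁴ steps.
* Kabsch superposition uses the SVD with the determinant sign
  correction; degenerate inputs (< 3 atoms, mismatched counts) error.
  RMSD with `fit = FALSE` measures in the given frames.
* The lattice is 6-connected by default (26-connectivity available);
  activation ties break to the lowest linear index.
* Frontier exhaustion (no latent particles left) stops a run early with
  status `"frontier_exhausted"` rather than erroring.
* Histogram bins start at the data minimum; the maximum falls in the
  last bin; probabilities always sum to 1.
* PCA retains singular values above a 10⁻¹² relative threshold; a
  two-frame trajectory yields one mode.

## Reported-count conventions

"n particles" in cast summaries means the total active set including
the seed; the activation-event counter excludes the seed, so a 400 ps
run at one activation per ps reports 400 events and 401 active
particles.

## Problem sizes

The shipped validation studies are sized for a desk machine: the
soft-axis study uses 260 shell beads, 150 activations per run at a
0.25 ps interval, and ten seeds; the scheduler-contract check runs the
full 400-event schedule on a free lattice with interactions disabled
(the count is a property of the schedule alone); drift detection uses
100 synthetic 400-frame projection sets. A faithful 400 ps / 115 ps-ramp
pocket run with the default protocol is what `scripts/acceptance.R`
executes.

## Known limitations

* Protein-free growth under the minimum-force rule is *directionally*
  unbiased (over 20 seeds the mean cast-centroid displacement from the
  seed is below one lattice spacing) but not compact: with probes
  feeling the active particles, anchor-tethered thermal wander makes
  low-coordination tip sites systematically cheapest, so free-space
  casts are loose dendritic clusters (gyration elongation ~2–3 at 150
  events rather than ≈ 1). In a confined pocket — the method's actual
  regime — the wall gradient dominates and this effect is irrelevant,
  but shape statistics of unconfined casts should not be read as
  sphere-like.
* The elastic network cannot rearrange side chains or break contacts;
  stage-2 behaviour (side-chain accommodation) is represented only as
  generic compliance.
* No solvent: "expansion toward solvent" appears here as growth into
  empty lattice regions.
* The homology-model, all-atom and QM machinery that produced the
  original kinase numbers is out of scope; kinase-specific values are
  not reproduced by this package and its fixtures.
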