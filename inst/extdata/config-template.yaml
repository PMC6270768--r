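# pocketcast run configuration template.
# Every key is optional; omitted keys use the method defaults shown here.

structure:
  # Either a PDB file ...
  path: null
  # ... or a built-in toy pocket (arguments of make_toy_pocket()):
  toy_pocket:
    n_shell_atoms: 260       # shell beads forming the two-layer pocket wall
    cavity_radius: 4.4       # empty cavity radius, A
    soft_axis: [1, 0, 0]     # soft expansion direction
    stiffness_ratio: 1.0     # soft/hard spring ratio (1 = isotropic)
    seed: 1

mask:
  ranges: null               # core residue-range tokens, e.g. ["7L-33K"]
  chain: A
  include_o: false           # add backbone O atoms to the mask

grid:
  center: [0, 0, 0]          # binding-site centre, A
  edge: 15                   # box edge, A (volume window 3375-8000 A^3)
  spacing: 1.1               # lattice spacing, A (method default)
  particle_mass: 10          # cast-particle mass, Da (method default)
  restraint_k: 0.1           # lattice anchor constant, kcal/mol/A^2

lj:
  eps: 0.1                   # LJ well depth, kcal/mol (soft particles)
  rmin: 1.4                  # particle-particle equilibrium distance, A
  rmin_protein: 3.0          # protein-atom LJ size contribution, A
  cutoff: 10                 # non-bonded cutoff, A

engine:
  dt: 1                     # integration step, fs (method default)
  duration: 400             # pressurisation length, ps (method default)
  activation_interval: 1    # one activation per interval, ps
  temperature: 300          # target temperature, K
  ramp_time: 115            # heating/restraint-release ramp, ps
  thermostat_friction: 1    # Langevin collision frequency, 1/ps
  thermostat: langevin      # langevin | none
  adjacency: 6              # lattice connectivity (6 or 26)
  particle_lj: true         # particle-particle LJ active
  latent_feel_active: true  # latent probes feel active-particle LJ
  ramp_restraint_k: 100     # initial protein restraint, kcal/mol/A^2

analysis:
  rmsf: true
  rmsd: true
  com_distance: null        # e.g. [14, 146] for a P-loop/DFG-type distance
  histogram_bin_width: 0.25 # A
  stages: true
  n_segments: 4
  pca: true
  n_modes: 10
  trajectory: null          # defaults to <output_dir>/trajectory.pdb

output_dir: asp-output
seed: 1
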