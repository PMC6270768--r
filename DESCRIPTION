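Package: pocketcast
Title: Grid-Based Active Site Pressurisation and Binding-Pocket
    Flexibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Probes the intrinsic flexibility of protein binding pockets by
    growing a cast of restrained, uncharged Lennard-Jones particles on a
    cubic lattice inside the cavity (active site pressurisation): forces on
    latent grid particles adjacent to the cast are accumulated over short
    dynamics intervals and the particle under least force is activated, so
    the cast expands along the energetically softest directions of the
    pocket. Includes a desk-scale coarse-grained force model
    (elastic-network protein, Lennard-Jones particles, harmonic grid
    restraints) with a velocity-Verlet/Langevin integrator, backbone
    core-mask construction from printed residue ranges, trajectory analyses
    (RMSF, multi-reference RMSD series, centre-of-mass distance
    distributions, piecewise-linear stage segmentation, latent-force maps,
    gyration-tensor cast shape descriptors), principal component analysis
    of backbone covariance with eigenvector-overlap comparison and
    drift-mode detection, and seed-deterministic synthetic fixtures
    (kinase-like backbones, shell pockets with a tunable soft expansion
    axis, trajectories with planted modes).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
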