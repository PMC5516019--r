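Package: multibind
Title: Concentration-Dependent Ligand Binding to Multiple Saturable Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical-mechanical analysis of small-ligand binding to
    multiple independent, saturable sites on a membrane protein. Converts
    per-site restrained free-energy-perturbation work values and harmonic
    restraint constants into equilibrium binding constants and standard
    binding free energies, enumerates occupancy-state probability
    distributions as a function of reservoir concentration, computes
    titration curves, marginal and macrostate occupancies, symmetry-class
    averaged affinities for oligomeric receptors, resolves binding sites by
    clustering docking-pose centroids, and maps occupancy probabilities into
    one- and three-dimensional ligand number densities (OpenDX export).
    Includes seeded synthetic-data generators (affinity tables, harmonic
    pose clouds, a Metropolis occupancy sampler) used as independent oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    bio3d,
    optparse
Config/testthat/edition: 3
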