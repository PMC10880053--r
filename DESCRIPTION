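Package: polylobe
Title: Self-Assembly Simulations of Polydisperse Lobed Patchy Colloids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained rigid-body Langevin dynamics (NVT ensemble) for
    lobed patchy colloids with polydisperse lobe sizes, together with the
    structural analysis suite used to characterise their self-assembly:
    radial distribution functions, relative neighbor orientation
    distributions, per-lobe bond statistics, bond-network clusters and a
    voxel-based pore-size-distribution (largest included sphere) analysis.
    Particles are built from a repulsive seed sphere and attractive lobe
    spheres whose diameters are drawn from a truncated Gaussian; pair
    interactions are a surface-shifted Lennard-Jones repulsion and a
    truncated-and-shifted Lennard-Jones attraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
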