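Package: ramafield
Title: Residue-Specific Ramachandran Distributions from a Steric and
    Lennard-Jones Mean Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds amino-acid residue mimetic structures (alanine, valine,
    leucine, isoleucine) from idealized internal coordinates, performs
    exhaustive nested side-chain torsion scans over Ramachandran space to
    compute average hard-sphere overlap counts and average intramolecular
    Lennard-Jones energies, combines the Lennard-Jones mean field with an
    empirical backbone-water free-energy surface derived from a Gaussian
    mixture model, and converts the combined field to Ramachandran
    probability distributions via Boltzmann inversion.  Distributions are
    summarized as mesostate populations and ensemble-averaged Karplus
    J-couplings, with reading and writing of mimetic structures as PDB
    files carrying CONECT bond records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
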