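Package: micellar
Title: Structural Analysis of Surfactant Micelles from Simulation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-micelle coordinate trajectories of nonionic
    alkylphenol ethoxylate (Triton X type) surfactants in water: radius of
    gyration and inertia-tensor shape metrics (Imax/Imin, eccentricity,
    average micelle radius), solvent-accessible surface area with
    hydrophilic/hydrophobic decomposition via a rolling 1.4 Angstrom probe,
    radial probability profiles of labelled atom positions about the micelle
    centre of mass, radial distribution functions and cutoff hydration
    numbers, geometric hydrogen-bond detection and the intermittent
    hydrogen-bond time correlation function. Includes GRO/PDB readers and
    writers, periodic-boundary geometry (minimum image, micelle unwrapping),
    molecular templates for TX-5/TX-114/TX-100, and a deterministic synthetic
    micelle generator so the whole pipeline is testable without a molecular
    dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
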