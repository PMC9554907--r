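Package: vesigrid
Title: Spherical Grid Surface Fitting and Morphometrics for Closed Molecular Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits smooth, fully differentiable spherical grid surfaces to
    atomic point clouds of closed chemical interfaces (vesicle leaflets,
    micelles, pore walls) by Gaussian-weighted geodesic interpolation, and
    computes curvature-dependent structural properties: surface area,
    enclosed volume, sphericity, area and volume per lipid, membrane
    thickness maps, radial number-density profiles, curvature order
    parameter, principal moments of inertia and roundness indices.  Also
    characterizes crystalline porous materials by Monte-Carlo geometric
    void fraction and pore metrics.  Includes synthetic fixture generators
    with analytic ground truth and a command-line interface for per-frame
    trajectory analysis of multi-MODEL PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
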