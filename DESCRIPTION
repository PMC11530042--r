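Package: vancoelute
Title: Finite-Difference Simulation of Local Vancomycin Release and
    Distribution from Polymer-Coated Bone Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explicit finite-difference simulation of Fickian diffusion with
    first-order (half-life) clearance in layered tissue and bone geometries,
    driven by a cumulative drug-release profile converted to a flux boundary
    condition. Provides effective-diffusivity estimation for porous bone
    (constrictivity, porosity, tortuosity), stability-bounded time stepping
    with a full mass ledger, one- and two-dimensional scenario runners
    (in vitro slab release, agar inhibition-zone assay, rat tibia bolus,
    human bone-plate delivery), minimum-inhibitory-concentration and toxicity
    zoning, inhibition-area and summary statistics, a log-normal
    percentile-based parameter sensitivity workflow, and seeded synthetic-data
    generators for release profiles and noisy concentration series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
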