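Package: aquaflux
Title: Water Permeation Counting and Gating-State Flux Modelling for
    Aquaporin Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking the conformational states of
    pore-lining residues to single-file water permeability in aquaporin
    family channels, developed around the E. coli aquaglyceroporin GlpF.
    Counts complete water permeation events through a per-protomer
    cylinder from molecular dynamics trajectories, classifies nine
    pore-lining residues into gating states from side-chain dihedrals and
    minimal distances, bins simulations into lagged property/flux interval
    pairs, and fits a Bayesian negative-binomial multilevel model with a
    varying intercept per pore that predicts water flux per residue state.
    A synthetic-data module generates gating-state traces, flux counts
    with known ground truth, and toy three-dimensional water trajectories
    with planted permeation events for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    coda,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
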