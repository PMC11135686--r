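Package: liebigsmad
Title: Receptor-Limited TGF-beta/SMAD Signaling Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinetic models of TGF-beta/SMAD signal transduction built around
    the minimum principle: pathway output tracks whichever of the two TGF-beta
    receptor types (TGFBR1, TGFBR2) is less abundant. Provides an analytic
    two-reaction equilibrium model with receptor-space landscape scans, a
    mass-action ODE model of the full pathway (ligand depletion, receptor
    trafficking, negative feedback, SMAD2 nucleocytoplasmic shuttling),
    derived immunoblot- and imaging-style observables, expression-space
    sampling, heterogeneous single-cell population simulation with correlation
    analysis, receptor-knockdown dose-response prediction with Hill/EC50
    fitting, multistart least-squares parameter estimation with
    profile-likelihood identifiability, and synthetic-data generators with
    known ground truth for closed-loop validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
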