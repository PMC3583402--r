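Package: mtpolsim
Title: Stochastic Simulation of RNA Polymerase Traffic on Circular Mitochondrial DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven stochastic simulation of phage-type RNA polymerase
    binding, elongation, collision and factor-dependent termination on circular
    mitochondrial genomes. Promoter and factor binding attempts follow Poisson
    processes; elongation is deterministic; a polarized protein-dependent
    terminator (mTERF) stops polymerases directionally with passage
    probabilities p and q. The package turns simulated trajectories into
    per-gene transcription levels and terminator statistics, compares them to
    experimental relative RNA concentrations and half-lives with an
    absolute-error calculus, fits promoter and factor intensities to
    experiment by a stop-at-boundary coordinate search ("active search"),
    and includes a closed-form model of polysomal mRNA protection against
    ribonuclease decay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
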