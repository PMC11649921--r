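Package: tailchase
Title: Deadenylation and Decay Kinetics from Poly(A)-Tail Chase Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of mRNA poly(A)-tail length distributions in
    transcription/export-block chase experiments measured by nanopore direct RNA
    sequencing. Fits a Pab1-protection-modified gamma distribution to per-read
    tail-length profiles, solves the coupled first-order kinetics of distributive
    tail shortening (numerically and in closed Poisson-convolution form), converts
    apparent per-position decay rates into the microscopic enzymatic deadenylation
    rate, estimates per-transcript deadenylation and mRNA decay rates from quantile
    tail-length trajectories, and ships a synthetic chase generator so every
    estimator can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
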