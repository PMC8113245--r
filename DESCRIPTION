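Package: gpcsim
Title: Compile and Simulate Tandem Recombinase Gene-Perturbation-Cassette Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing tandem arrays of self-excising gene perturbation
    cassettes (GPCs) driven by chemically induced dimerization of split
    site-specific recombinases (Cre/loxP, Flp/FRT, PhiC31/att). A compiler turns a
    declarative circuit design into annotated DNA constructs, enumerating every
    post-excision stage with scar bookkeeping, reading-frame checks and PCR
    amplicon prediction. A continuous-time stochastic simulator propagates cell
    populations through alternating two-ligand schedules with expression-gated
    excision, ligand-free leak, antibiotic synchronization and attP-mediated
    self-deletion, alongside a closed-form Markov occupancy oracle. Assay models
    convert simulated populations into flow-cytometry fractions, scar-amplicon
    sequencing with PCR length-bias correction, CRISPR indel-accumulation
    kinetics with post-excision sgRNA lag, and qPCR circuit-removal ratios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
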