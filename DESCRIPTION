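Package: ggaffinity
Title: Predicting CsrA/RsmE Binding Affinity of RNA GGA Motifs from
    Sequence and Secondary-Structure Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans RNA sequences with known secondary structure for GGA
    motifs of the CsrA/RsmE class of translational regulators, classifies
    each motif's structural context (hexaloop on a stem, purine pentaloop,
    pentaloop without the looped-out nucleotide, expanded loop,
    single-stranded, partially or fully base-paired) and assigns a
    dissociation-constant tier spanning five orders of magnitude
    (about 10 nM to 3 mM). Also provides the binding-thermodynamics
    machinery behind such affinity measurements: forward simulation and
    least-squares fitting of one-site and sequential two-site isothermal
    titration calorimetry isotherms with enthalpy/entropy decomposition, a
    slow-exchange NMR peak-integral dissociation-constant estimator, and an
    equilibrium sequestration model of protein-site partitioning among
    mRNA ribosome-binding sites and decoy small-RNA motifs that predicts
    translation repression and de-repression rank orders. Seeded synthetic
    generators produce structured RNAs with planted motifs, noisy
    calorimetry thermograms and NMR integral pairs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
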