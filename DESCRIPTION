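Package: anaflow
Title: Confined Cytoplasmic Flows and Anaphase Chromosome-Separation Scaling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and quantifies the cytoplasmic flows that separate
    chromosomes during anaphase B in early embryonic cleavage divisions.
    Implements a two-dimensional regularized-Stokeslet solver for creeping
    flow confined by a no-slip cell boundary, driven by force dipoles that
    arise from dynein-transported cargo dragging on asymmetric microtubule
    asters; an anaphase simulation that advances asters and chromosomes
    through these flows and predicts where nuclear envelope reformation
    (NER) occurs as a function of cell length; an exponential
    dephosphorylation timing model that converts phospho-histone thresholds
    into NER times; particle image velocimetry (multipass FFT correlation
    with CLAHE preprocessing) for flow fields from time-lapse image stacks;
    two-regime mean-square-displacement analysis of organelle tracks; and
    seeded synthetic-data generators (phospho traces, two-phase tracks,
    particle movies) so every stage can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'friction.R'
    'domain.R'
    'stokes.R'
    'aster.R'
    'simulate.R'
    'timing.R'
    'tracks.R'
    'piv.R'
    'synthetic.R'
    'cli.R'
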