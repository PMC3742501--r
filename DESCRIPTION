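Package: vocrep
Title: Quantitative Analysis of Graded and Discrete Vocal Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for describing animal vocal repertoires from annotated
    recordings and for testing how calls encode the situation of emission.
    Extracts spectral call features (peak frequency, median frequency q50,
    Wiener entropy, frequency-modulation measures) from WAV audio, assesses
    discreteness of the repertoire with k-means cluster-validity curves
    (EtaK/PreK), classifies calls to situations by linear discriminant
    analysis with label-permutation and individuality-controlled (pDFA)
    significance testing, relates call types to situations via chi-square
    association with Pearson residuals and Ward dendrograms, and models the
    link between expert-rated situation valence and call structure with
    Spearman correlations and quasi-binomial regression under false
    discovery rate control. Includes a seeded synthetic-call generator
    (waveforms and feature tables) emulating a multi-situation piglet
    recording study, so the whole pipeline is testable without field
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, grDevices, graphics, ape, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
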