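Package: ShapeCovar
Title: Covariation Between Transcription Factor Sequence and DNA Binding-Site Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of covariation between the amino-acid sequences of a
    transcription factor family and the nucleotide sequence and 3D shape of
    their DNA binding sites. Provides pentamer-table DNA shape prediction
    (minor groove width, propeller twist, roll, helix twist), alignment of
    protein binding microarray 8-mers to a degenerate core consensus, position
    frequency matrix construction, BLOSUM-based protein similarity, matrix
    level correlation with shuffle and binning controls, per-position
    hypergeometric and mutual-information covariation maps, residue-grouped
    minor groove profiles, and a shape-augmented cross-validated linear model
    of binding affinity, together with a synthetic-data generator that plants
    controllable sequence/shape covariation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
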