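Package: txtomo
Title: Transcriptome Tomography: 3D Gene-Expression Maps from Serial Tissue Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional gene-expression density maps from
    per-fraction expression measurements taken on serial tissue slabs cut along
    multiple body axes (pseudo-back-projection with multi-series averaging),
    together with phantom-sphere validation of spatial accuracy, probe-level
    variance statistics (one-way ANOVA with Benjamini-Hochberg correction and
    I/V classification), and marker-gene-defined area quantification. Includes
    a seeded synthetic-data generator emulating a six-series, 61-fraction
    whole-brain sectioning design so the full pipeline runs without external
    data, plus NIfTI/NRRD volume input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    RNifti,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
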