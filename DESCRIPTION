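Package: coexatlas
Title: Atlas-Based Quantification of Brain-Wide Co-Expression of Two Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number, anatomical distribution and
    neurotransmitter phenotype of cells co-expressing two genes of very
    unequal prevalence (the ghrelin receptor Ghsr and the cannabinoid
    receptor Cnr1) by combining a deep single-cell RNA-seq dataset with a
    spatially resolved dataset that shares its cluster taxonomy. Provides
    per-cell positivity calling (log2 CPM threshold or raw counts),
    per-cluster positive fractions, apportionment of those fractions onto
    anatomical structures via the spatial cluster composition,
    partial-volume correction, literature-calibrated whole-brain scaling
    by through-origin regression, structure selection and Table-1-style
    region summaries, together with a synthetic paired-dataset generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
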