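Package: h3tailquant
Title: Targeted Middle-Down Quantification of Histone H3K4 Methylation
    with Kinetic and Binding-Curve Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the stoichiometry of H3K4 methylation (me0-me3)
    within each histone H3 tail acetylation degree (0ac-5ac) from targeted
    middle-down mass spectrometry runs, using the C4+1 ETD fragment ion
    series of the Glu-C H3 N-terminal peptide. Provides exact monoisotopic
    mass and fragment m/z computation for PTM-decorated proteoforms, a
    ground-truth-labelled synthetic run generator for benchmarking, scan
    selection and spectral averaging, replicate aggregation with
    technical-within-biological designs, and condition comparison.
    Also implements steady-state methyltransferase kinetics (Hill and
    Michaelis-Menten fits with extra sum-of-squares model selection) and
    four-parameter-logistic dose-response analysis with relative EC50,
    generalized EC_F, and hook-point exclusion for bead-proximity assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
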