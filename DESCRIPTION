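Package: fragkin
Title: Fragment-Contribution Models for Human Skin Permeability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the human skin permeability coefficient (logKp, log10
    cm/s) from counts of ten functional groups using published
    group-contribution equations, and refits such models from permeability
    tables. Counts fragments by SMARTS matching on SMILES input, evaluates a
    registry of published equations (two global/scenario equations, 27
    scenario-stratified models, a mean baseline and the DERMWIN comparator),
    fits new models by ordinary least squares via the normal equations with a
    per-coefficient significance criterion and top-down elimination, applies
    HuskinDB-style record selection and scenario stratification rules, and
    generates synthetic fragment-count datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Cheminformatics, Regression, QSAR
RoxygenNote: 7.3.3
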