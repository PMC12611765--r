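Package: epilipidR
Title: Semi-Targeted Epilipidomics: Oxidized Lipidome Prediction,
    Identification and Targeted Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for semi-targeted epilipidomics of oxidized neutral and
    polar lipids. Implements lipid shorthand parsing and elemental-formula
    arithmetic, in silico enumeration of oxidized lipid species under
    combinatorial modification constraints, inclusion- and iterative
    exclusion-list generation for data-dependent acquisition, rule-based
    identification of oxidized lipids from centroided MS/MS spectra with
    Kendrick mass defect-retention time false-positive filtering, extracted
    ion chromatogram and parallel reaction monitoring quantification with
    internal-standard, protein and isotope-dilution normalization,
    MetaboAnalyst-style statistics (log10 transform, autoscaling, Welch
    t-tests with FDR control, hierarchical clustering), analysis of
    inhibited-autoxidation kinetic traces, and seeded synthetic-data
    generators for every input so the full pipeline is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0),
    S4Vectors,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'masses.R'
    'AllClasses.R'
    'formula.R'
    'adducts.R'
    'kendrick.R'
    'lipid-parse.R'
    'lipid-formula.R'
    'epilipidome.R'
    'acquisition.R'
    'fragments.R'
    'identification.R'
    'quantification.R'
    'calibration.R'
    'lipidome-table.R'
    'statistics.R'
    'kinetics.R'
    'synthetic-data.R'
    'io.R'
    'pipeline.R'
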