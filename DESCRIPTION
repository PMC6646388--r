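Package: mrmpanel
Title: Design and Validation of Targeted LC-MRM-MS Peptide Transition Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and validating targeted proteomics
    (LC-MRM-MS) assays for bacterial protein biomarkers, developed around
    the monitoring of Dehalococcoides mccartyi reductive-dechlorination
    biomarkers in groundwater. Covers in-silico tryptic digestion and
    proteotypic-peptide filtering, precursor and y-ion m/z and
    collision-energy calculation, transition-list export, cross-proteome
    peptide specificity screening with three-tier classification,
    AUC-based transition ranking and cross-strain panel assembly, and
    rule-based validation of peptide detections in MRM chromatograms
    (co-elution, transition intensity dot-product, replicate
    reproducibility, spike-in standard agreement). Includes a seeded
    synthetic-data generator producing proteomes with planted peptides and
    Gaussian-peak chromatograms with decoy corruptions for end-to-end
    testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
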