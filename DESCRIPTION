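Package: modstoich
Title: Site-Specific RNA Modification Stoichiometry from LC-MS with
    Isotope-Labeled Internal Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the stoichiometry of site-specific RNA
    modifications (2'-O-methylation, pseudouridylation, base methylation)
    from LC-MS data of ribonuclease digests.  Implements
    modification-aware in-silico digestion by RNase T1, RNase A and
    guided RNase H splitting; oligonucleotide elemental composition,
    monoisotopic mass and negative-mode m/z computation with
    13C-labeled internal-standard channels; MS1/MS2 identification of
    digest species with isobar handling; and two stoichiometry
    estimators (light/heavy intensity ratio with an experimental mixing
    correction factor, and extracted-ion-chromatogram peak-area
    fractions) with replicate aggregation and condition comparison.  A
    synthetic LC-MS data generator provides ground-truth scenarios for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
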