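Package: cimion
Title: Molecular Ion Recognition and Formula Assignment for GC Methane
    Chemical Ionization Mass Spectra
Version: 0.1.0
Authors@R:
    person("cimion", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gas chromatography accurate-mass spectrometry under
    methane chemical ionization (CI) of trimethylsilylated (TMS) metabolites.
    Recognizes the characteristic cluster of molecular ion species
    ([M-CH3]+, [M-H]+, [M]+, [M+H]+) together with the reagent-gas adducts
    [M+C2H5]+ and [M+C3H5]+ in centroided spectra, deduces the neutral
    monoisotopic mass, and assigns elemental formulas over C/H/N/O/P/S/Si by
    bounded accurate-mass decomposition with valence and isotope-pattern
    filters. Includes exact-mass derivatization arithmetic (TMS,
    methoximation), readers and writers for MSP, CSV, MGF and SIRIUS MS
    formats, a synthetic CI spectrum generator with ground truth, and an
    evaluation harness for detection and formula-ranking accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
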