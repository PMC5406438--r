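Package: cepka
Title: Acid Dissociation Constants and Supramolecular pKa Shifts from
    Capillary Electrophoresis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determination of acid dissociation constants (pKa), their
    host-induced supramolecular shifts, and dissociation thermodynamics
    from capillary-electrophoresis migration-time data. Implements
    electrophoretic mobility computation with voltage-ramping correction,
    a two-section Joule-heating temperature estimate with re-referencing
    of mobilities to temperatures of interest (double correction
    strategy), classical sigmoid pKa fitting, the closed-form two-values
    method, a spectrophotometric absorbance-ratio (beta) method for
    ionized hosts, Van't Hoff extraction of dissociation enthalpy and
    entropy, and a synthetic CE-run simulator providing ground truth for
    every estimation stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
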