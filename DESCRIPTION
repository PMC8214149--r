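Package: xlmsn
Title: MSn-Based Identification and Validation of Sulfoxide-Cleavable
    Cross-Linked Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An MSn (multistage mass spectrometry) pipeline for peptides
    cross-linked by sulfoxide-containing MS-cleavable reagents, covering the
    amine-reactive DSSO and the heterobifunctional photoactivated NHS-diazirine
    linkers SDASO-L/-M/-S. Provides elemental-formula mass arithmetic and a
    remnant-moiety registry, in-silico protease digestion with decoy databases,
    a synthetic MSn spectrum generator with truth manifests and toy structure
    ensembles, MS2 signature-ion pair detection, MS3 peptide-spectrum matching
    with neutral-loss handling and site-localization ambiguity, cross-link
    assembly with target-decoy FDR estimation, Calpha-Calpha distance
    validation against multi-state structure models with a random-distance
    null, and the ambiguity-weighted amino-acid preference statistic for
    diazirine labeling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    bio3d,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
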