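Package: abvalidate
Title: Five-Pillar Enhanced Validation of Western Blot Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Decision pipeline for enhanced validation of Western blot
    antibodies using five complementary strategies: orthogonal correlation
    of band intensities with antibody-independent abundance measurements
    (RNA-seq TPM, PRM ratio-to-standard, TMT intensities), capture
    mass-spectrometry "virtual Western" concordance between band position
    and gel-slice peptide profiles, genetic knockdown, recombinant
    overexpression, and comparison of independent antibodies with
    non-overlapping epitopes. Includes an SDS-PAGE molecular-weight model
    (ladder calibration, theoretical protein masses, dominant-band
    analysis), per-pillar decision rules with configurable thresholds,
    aggregation into enhanced/uncertain/not-done validation reports, and
    seeded synthetic-data generators with ground-truth labels for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
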