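Package: mwfp
Title: Multi-Wavelength HPLC Fingerprint Fusion and Quantified Similarity Grading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geographical-origin identification of herbal materials from
    HPLC-DAD fingerprints. Implements signal-level fusion of chromatograms
    recorded at several detection wavelengths, peak detection and
    cross-sample matching into co-possessing-peak fingerprint matrices,
    averagely linear quantified fingerprint similarity parameters with
    eight-level grading, hierarchical clustering with between-groups
    linkage on squared Euclidean distances, principal component analysis,
    orthogonal projections to latent structures discriminant analysis with
    variable-influence-on-projection scores, linear calibration and saponin
    quantitation, and a deterministic synthetic-study generator emulating a
    32-batch two-origin Panax notoginseng design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
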