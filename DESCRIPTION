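Package: emgbilat
Title: Bilateral Surface-EMG Symmetry Indexes for Motion Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assessment of bilateral symmetric motions from multichannel
    surface electromyography. Implements the standard sEMG conditioning
    chain (20 Hz high-pass, full-wave rectification, 32 Hz low-pass,
    fifth-order Butterworth, session-median standardization), a power
    decomposition of each body side into per-muscle coordination
    coefficients, and two per-trial symmetry indexes: Effective Strength
    Balance (normalized right-left power difference) and Muscle
    Coordination Similarity (correlation of the two sides' coefficient
    vectors). Includes a seeded synthetic bimanual-EMG generator with
    ground-truth coordination and strength parameters, muscle
    activity-print boxplot statistics, and cohort-level rank-sum
    comparisons with Holm correction.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    data.table,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
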