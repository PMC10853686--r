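Package: gmunits
Title: An Anchored Universal Measurement Scale for Gross Motor Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and using an anchored interval scale of
    gross motor task difficulty, the Gross Motor (GM) unit. Implements an
    ordinal three-component rating schema (body position, movement, support)
    for gross motor tasks, a regression-based specification equation that
    predicts task difficulty from the component ratings (with Pearson
    screening, variance-inflation-factor diagnostics and forward stepwise
    ordinary least squares), and an anchoring transform that fixes a 0-100
    interval scale between lying supine and unsupported walking. A partial
    credit model simulator and joint-maximum-likelihood item calibrator
    provide synthetic observed difficulties so the whole derivation pipeline
    can be exercised and validated end to end. The 66-item GMFM-66 component
    rating table and its GM-unit reference table are bundled as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
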