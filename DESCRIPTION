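Package: sknaer
Title: Burst Detection and Quantification of Skin Sympathetic Nerve Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies bursts of skin sympathetic nerve activity
    (SKNA) in high-rate body-surface biopotential recordings. Signals are
    band-pass filtered to 500-1000 Hz and enhanced with the Teager-Kaiser
    energy operator; burst candidates are segmented by an envelope threshold
    and refined on a short-window integral signal; residual ECG (QRS) energy
    and sub-threshold-duration events are relabelled as artifacts. Provides
    the SKNA energy ratio (SKNAER, dB) and average iSKNA features, the
    classical integrated-SKNA threshold detector as a comparator, segment-level
    evaluation against expert annotations (detection rate, precision,
    coincidence), reference heart-rate-variability features, and a synthetic
    recording generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
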