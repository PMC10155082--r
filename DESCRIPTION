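Package: mobsense
Title: Passive-Sensing Mobility and Wi-Fi Features with Symptom Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts mobility features (density-based location clusters,
    location entropy, normalized entropy, daily travel distance) from raw
    smartphone GPS fixes and Wi-Fi usage features (session time, public vs
    private network shares) from Wi-Fi connection logs, then fits
    covariate-adjusted linear models associating these features with
    depression (PHQ-9) and PTSD (PCL-5) symptom severity. Ships a synthetic
    cohort generator with known ground truth so the entire pipeline is
    testable without access to sensitive participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
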