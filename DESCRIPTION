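Package: crcscreen
Title: Case-Based Survival Estimation and Risk Stratification for
    Colorectal Cancer Screening Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clinical decision support for colorectal-cancer (CRC)
    screening registries. Encodes patients against a minimum data set
    codebook, converts Persian-calendar birthdates, classifies hereditary
    risk with Amsterdam II and revised Bethesda rule engines, recommends
    surveillance schedules, and estimates per-patient survival percent by
    cosine similarity to deceased registry members, keeping per-subgroup
    statistics consistent as the registry changes. Includes a synthetic
    registry generator with planted prognosis structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
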