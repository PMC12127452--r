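Package: pitt
Title: Parcel-Level Crop Classification from SAR Time Series and
    High-Resolution Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Grades irregular agricultural parcels by the radius of their
    maximum inscribed circle on a SAR pixel grid, classifies larger parcels
    from medium-resolution backscatter time series via a
    clustering-to-classifier pseudolabel pipeline (k-Shape prototypes fine-tuned
    with phenology references, then an InceptionTime-family network), classifies
    tiny parcels from high-resolution texture chips via pseudolabel-refined
    semi-supervised texture classification, and fuses the two probability
    streams by weighted averaging. Includes time-weighted dynamic time warping,
    phenological time-series representativeness statistics (GAS/TAS), and a
    synthetic scene generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
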