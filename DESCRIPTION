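Package: synlethal
Title: Synthetic-Lethal siRNA Enhancer Screens, Gene-Set Enrichment and
    Drug-Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for synthetic-lethal siRNA
    drug-enhancer screens. Normalizes plate-format viability readouts,
    computes siRNA-by-drug interaction ratios and calls enhancer hits
    through a multi-round screening funnel; tests hit lists for pathway
    over-representation with an exact hypergeometric model (including a
    utility that calibrates the unknown annotation universe behind
    published p-values); ranks expression profiles and computes weighted
    Kolmogorov-Smirnov enrichment scores with permutation p-values and
    leading-edge subsets; fits the median-effect dose-response model and
    quantifies drug-drug synergy with the Chou-Talalay combination index
    and normalized isobolograms. Ships simulators for every input type
    with planted ground truth, so the whole chain can be validated by
    truth recovery.
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
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
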