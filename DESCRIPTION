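Package: deeproot
Title: Deep-Rooting Traits and Isotope Tracer Accounting for Minirhizotron Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts minirhizotron image observations from inclined-tube
    semi-field phenotyping facilities into depth-resolved root profiles and
    deep-rooting traits (the cumulative DeepRoot40 statistic, sigmoid
    inflection rooting depth, planar root length density and depth-interval
    root lengths), performs stable-isotope tracer accounting (delta to atom
    fraction conversion, 15N excess mass balance, per-row dose partitioning
    and percent tracer recovery), and links deep rooting to deep water and
    nitrogen uptake through genotype-mean estimation and cultivar-mean
    Pearson correlation analyses. A synthetic-trial generator with known
    ground truth makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
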