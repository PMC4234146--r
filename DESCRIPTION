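Package: wamindex
Title: Asset-Based Wealth Indices and the WAMI Socioeconomic Index for
    Multicountry Child Health Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and comparing household socioeconomic
    status (SES) measures in multicountry child health surveys. Implements
    four wealth measures -- maternal education, principal components analysis
    of the tetrachoric correlation matrix of binary asset indicators, an
    adapted household-level Multidimensional Poverty Index, and a summed
    asset score whose assets are selected by random-forest conditional
    permutation importance -- together with the composite WAMI index
    (Water/sanitation, Assets, Maternal education, Income). Includes
    indicator screening by Cronbach's alpha, a validation framework
    (cross-validated prediction error against child height-for-age Z-scores,
    adjusted R-squared with site indicators, scaled effect sizes, income
    construct-validity checks), and a seeded synthetic multicountry cohort
    generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
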