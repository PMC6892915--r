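Package: imodkit
Title: Independently Modulated Gene Sets from Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes a gene-expression compendium into robust statistically
    independent components by repeated independent component analysis with
    correlation-distance clustering, thresholds components into independently
    modulated gene sets (i-modulons) via iterative D'Agostino K-squared
    pruning, links i-modulons to known regulons with Fisher's exact test under
    false-discovery-rate control, and uses the resulting basis for
    differential-activity testing, strain-difference correction, and
    projection of new expression profiles. Includes a synthetic-compendium
    generator with planted modules and a matching toy regulon table so the
    whole workflow can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
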