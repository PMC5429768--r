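Package: golgifc
Title: Quantification of Golgi Fragmentation from Imaging Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, scriptable pipeline for automated, non-subjective
    quantification of Golgi apparatus fragmentation from multispectral
    single-cell images of the kind produced by imaging flow cytometers.
    Provides threshold ('Threshold_60'/'Threshold_50') and object masks,
    intensity-weighted image-moment features (minor axis intensity, area),
    Fisher's-discriminant (RD) feature ranking, hierarchical gating of
    single focused cells into cell-cycle, mitotic-subphase, apoptotic and
    intact / partially fragmented / fully fragmented Golgi populations,
    a pulse-shape-analysis (PulSA) baseline, population summaries with
    replicate statistics, and a synthetic single-cell image generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
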