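Package: espanr
Title: Strand-Resolved Quantification of Parental Histone Segregation at
    Replication Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how parental and newly synthesized histones are
    partitioned between the leading and lagging strands of DNA replication
    forks from strand-specific nascent-chromatin sequencing (eSPAN).
    Computes Watson/Crick strand coverage at single-base resolution,
    per-origin sliding-window partition bias (W - C)/(W + C) with
    BrdU-input bias subtraction, and strand-resolved histone density
    coefficients with genotype fold changes and two-sample tests. Includes
    a replication-fork/histone-segregation simulator that generates
    stranded nascent-DNA fragment sets with known ground-truth recycling
    parameters, so every analysis stage can be validated against closed
    forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    ggplot2
Config/testthat/edition: 3
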