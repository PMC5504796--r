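Package: lipidrules
Title: Rule-Based Lipid Identification for LC-MS/MS Lipidomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates in silico fragmentation libraries for acyl-containing
    (including oxidized) lipids and annotates LC-MS/MS feature tables from
    data-dependent acquisition runs. Identification is rule based: candidate
    lipids are matched to features by exact precursor mass, MS/MS scans are
    assigned by retention-time and isolation-window tolerances, theoretical
    fragments are profiled across scans, per-class fragment rules assign
    confidence codes, and co-eluting candidates are ranked by summed fragment
    intensity. Includes a combiner that aligns annotation tables from
    different software by m/z and retention time, and a ground-truthed
    synthetic data generator for data-dependent tandem-MS experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
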