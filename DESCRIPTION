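Package: trflpr
Title: T-RFLP Profiling of Root-Associated Fungal Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for terminal restriction fragment length polymorphism
    (T-RFLP) analysis of root-associated fungal communities: in-silico
    restriction digestion of ITS amplicons, OTU clustering and rule-based
    mycorrhizal guild classification, peak-table matching into
    presence/absence community matrices, host genotyping summaries from
    binary ISSR band matrices, and the permutation-statistics layer used
    in fungal biogeography (distance decay, Mantel tests, occupancy
    distributions, envfit-style vector fitting with Holm-Bonferroni
    correction). Includes a seeded synthetic-study generator that plants
    host-genetic structuring of ericoid-mycorrhizal assemblages and
    geographic structuring of the remaining fungi, so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
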