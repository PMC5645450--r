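Package: cmapscreen
Title: Connectivity-Map-Style Compound Screening for Single-Gene
    Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end computational screen for compounds that perturb
    the expression of a single query gene, in the style of Connectivity Map
    drug repurposing. Replicate drug-treatment profiles are normalized
    against within-batch vehicle controls, converted to ranked gene lists,
    and merged per compound into a prototype ranked list (hierarchical
    Spearman-footrule/Borda rank aggregation). Compounds are scored by the
    query gene's rank within their signature, and drug-target compound sets
    are tested for concentration at either end of the resulting compound
    ranking with an unweighted Kolmogorov-Smirnov-type running-sum
    enrichment score, an empirical permutation null (randomized sets of
    matched size), two-tailed empirical p-values, and Benjamini-Hochberg
    false-discovery-rate control. A seeded synthetic-corpus generator with
    planted regulator compounds and target sets makes every stage testable
    without external data.
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
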