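Package: frailtykit
Title: Frailty-Index Scoring and Gut-Microbiota Response Analysis for
    Murine Stressor-Challenge Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a four-item, SD-threshold murine frailty index
    (body weight, grip strength, walking speed, exercise endurance) scored
    against a three-day baseline, with group comparison by ANOVA and
    Bonferroni-adjusted pairwise tests; genus-level gut-microbiota
    composition statistics (relative abundance, Shannon diversity,
    Bray-Curtis/PCoA ordination, Firmicutes/Bacteroidetes ratio, and
    directional per-genus challenge-response counts by Wilcoxon rank-sum
    test); and targeted-metabolomics class analysis (control-referenced
    Z-scores, class aggregates, NIPALS PLS-DA variable importance in
    projection, and VIP-gated volcano selection). A Dirichlet-multinomial
    and lognormal synthetic-data module generates behavioural, microbiome
    and metabolite datasets with planted ground truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    vegan,
    withr,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
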