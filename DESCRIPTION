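Package: famscreen
Title: Family-Based Rare-Variant Filtering and Cohort Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for gene discovery in small autosomal-dominant families
    and follow-up cohort screening, as applied to task-specific dystonias.
    Implements the per-family rare-variant filter cascade (exonic/splicing,
    protein-changing, rare, shared among affected members), cross-family
    candidate-gene intersection, segregation reporting with phenocopy and
    reduced-penetrance flags, per-cohort carrier tallies, and exact burden
    statistics (two-tailed Fisher exact test by hypergeometric probability
    mass, Pearson chi-square for category tables). A seeded simulator
    generates pedigrees, cohorts and VCF/PED/annotation fixtures with
    Mendelian transmission, configurable penetrance and phenocopy rates,
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
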