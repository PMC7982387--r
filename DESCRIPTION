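Package: rhizogeo
Title: Phylogeography and Symbiotic Effectiveness of Chickpea-Nodulating Rhizobia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilocus sequence analysis and spatial statistics for
    chickpea-nodulating Mesorhizobium collections: alignment site
    statistics, nucleotide (p and Tamura-Nei 1993), haplotype
    (allele-sharing) and genospecies distance matrices, reference-panel
    genospecies assignment, Shannon/Simpson diversity with a bootstrap
    resampling comparison, Mantel and partial Mantel permutation tests,
    principal coordinates analysis with coordinate-on-coordinate
    regression, a sliding-window isolation-by-distance resampler, and
    greenhouse symbiotic-effectiveness analysis (trait PCA, balanced
    variance components, Monte-Carlo Dunnett contrasts). Includes a
    seeded synthetic-data generator emulating the assumed population
    structure so the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
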