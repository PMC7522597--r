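Package: uraburden
Title: Ultra-Rare Variant Burden Testing for Case-Only Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene and gene-set burden testing of ultra-rare coding variants
    in case-only sequencing cohorts, without parental genomes or matched
    controls. Implements a quality/frequency/effect variant filter cascade,
    a one-sided binomial gene burden test based on per-gene de novo mutation
    probabilities globally rescaled so that expected and observed ultra-rare
    variant totals match, gene-set burden tests with per-subject capping,
    greedy step-down clustering of overlapping gene-sets by Jaccard
    similarity of their variant sets, a resampling-based false discovery
    rate, reference-singleton and protein-region exact-test enrichments,
    and prospective power calculations. Includes a synthetic cohort
    generator with known ground truth so the full pipeline can be exercised
    and calibrated without access to protected genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
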