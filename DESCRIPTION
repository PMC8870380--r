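Package: mmbacktrack
Title: Back-Tracking Somatic Variants in Serial Myeloma Precursor Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking somatic single-nucleotide variants and short
    indels backwards in time across serial bone-marrow samples from patients
    who progressed from a myeloma precursor condition (MGUS or smoldering
    myeloma) to overt multiple myeloma. Variants detected at the multiple
    myeloma timepoint are filtered through a targeted-panel cascade (coverage,
    variant allele frequency, consequence and pathogenicity class), then
    tested for presence in earlier precursor samples against an empirical
    background-noise null built from unrelated samples: a variant is called
    significantly present when its allele frequency exceeds the background
    mean by more than three standard deviations. Precursor samples in which a
    variant is not found are flagged for deep resequencing and re-tested.
    Includes a cohort simulator (binomial read sampling at two depth regimes,
    per-position error rates, clonal VAF growth) so the whole pipeline is
    testable end-to-end, plus cohort-level summary statistics and
    trajectory/swimmer-style reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    vcfR,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
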