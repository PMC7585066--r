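Package: semload
Title: Stochastic Epigenetic Mutation Calling and Epigenetic Mutation Load Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls stochastic epigenetic mutations (SEMs) from Illumina-style
    methylation beta matrices using per-CpG interquartile-range fences,
    aggregates them into epigenetic mutation load (EML) totals and
    region-, direction- and clock-specific variants, computes methylome
    Shannon entropy and residual epigenetic age acceleration from linear
    clocks, and relates these measures across cohorts via
    covariate-residualized biweight midcorrelation, Stouffer/Fisher-z
    meta-analysis, per-participant hypergeometric enrichment tests and a
    pathway-to-acceleration regression. Includes a synthetic-cohort
    generator with truth tables so the whole pipeline can be exercised
    without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
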