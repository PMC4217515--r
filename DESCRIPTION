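Package: pidpanel
Title: Variant Triage, Coverage QC and Concordance Analysis for Targeted
    Gene-Panel Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream analysis toolkit for amplicon-based targeted
    gene-panel sequencing in a diagnostic setting (e.g. primary
    immunodeficiency panels). Provides a threshold-based pileup variant
    caller, control-cohort background false-positive filtering
    (blacklisting of recurrent platform artifacts), rule-based triage of
    SNVs into high-confidence calls versus calls requiring orthogonal
    confirmation, region-level coverage quality control and clinical
    coverage reporting, base-resolution concordance against Sanger truth
    sets, paired nonparametric comparison of library-preparation
    protocols, and a Sanger-versus-NGS reagent cost model. A seeded
    synthetic-data module generates panels, references, depth profiles,
    read stacks and multi-sample runs with realistic capture
    non-uniformity so that every stage can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
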