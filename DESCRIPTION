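Package: ploidyExpress
Title: Expression-State Classification in a Sexual-Apomictic Ploidy Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ovule microarray experiments comparing
    sexual diploid and tetraploid genotypes against apomictic hexaploid
    hybrids across developmental stages. Provides probe summarization by
    median polish, quantile normalization, a sigma/sigma-max variance filter,
    PCA sample QC, stage-wise differential expression with fold-change and
    FDR gating, classification of genes into transgressive, parent-of-origin
    and ploidy (additive) expression states using two-standard-deviation
    bands around the parental groups, short time-series profile analysis with
    permutation significance for heterochrony detection, SNP-based parental
    origin screening, and delta-delta-Ct qPCR validation. A synthetic-data
    generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    cluster,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
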