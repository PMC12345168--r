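Package: rtpfactor
Title: Gene-Specific RNA-to-Protein Conversion Factors for Cross-Species
    Proteome Prediction
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating paired transcriptome and proteome
    abundance data from multiple microbial species: RPM and total-intensity
    normalization with detection filtering, mRNA-protein correlation
    structure (Spearman, R-squared, binned scatter summaries), essential
    versus non-essential gene contrasts with expression-matched controls,
    standardized-residual detection of genes with extreme protein-to-mRNA
    (ptr) ratios, and gene-specific RNA-to-protein (RTP) conversion factors
    transferred across species via single-copy orthologs, validated by
    leave-one-out cross-species prediction and a randomized null that
    preserves biologically plausible ptr ratios. Includes a synthetic-data
    generator emulating the statistical structure of multi-species paired
    omics studies, an exact Wilcoxon signed-rank test, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
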