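Package: smokesig
Title: Tobacco-Exposure DNA Methylation Signatures and Their Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies tobacco-exposure DNA methylation signature probes from
    Illumina 450K beta-value matrices and traces their regulatory context.
    Implements epigenome-wide prescreening (Wilcoxon rank-sum with
    Benjamini-Hochberg FDR control), an iterative PLS-DA "deep selecting"
    feature-elimination classifier with cross-validated stopping, robust
    probe-gene linkage through biweight midcorrelation and Spearman rank
    correlation under a two-threshold differential-correlation rule,
    soft-threshold gene weight networks with connectivity-based hub calling,
    and shortest-path betweenness tracing on weighted protein-protein
    interaction graphs with a permutation background filter. A synthetic-data
    generator with planted signal supports ground-truth validation of every
    stage without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
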