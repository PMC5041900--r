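Package: ithmeth
Title: Intratumoral Heterogeneity Analysis of Multi-Region Methylome and
    Mutation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paired pre-/post-treatment multi-region tumor studies
    that profile both the methylome (MethylCap-seq fragment counts over
    predefined methylation cores) and somatic mutations (targeted panel
    variant calls, copy number, B-allele frequencies).  Implements somatic
    variant filtering with homopolymer context, per-patient sharing
    classification (germline/truncal/shared/private) and candidate-driver
    calling; BAF-based loss-of-heterozygosity segmentation and a
    coverage-ratio copy-number caller; BioNJ phylogenies from Manhattan
    distances with driver-consistent branch labelling and per-patient
    clustering-concordance scoring; and a count-based differential
    methylation engine (log-CPM, quantile normalization, precision weights,
    empirical-Bayes moderated t, target-restricted Benjamini-Hochberg FDR,
    quantile-category hypermethylation calls).  A synthetic cohort generator
    with recorded ground truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    limma,
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
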