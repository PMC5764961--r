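Package: refstab
Title: Reference Gene Selection and Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identification and validation of reference (housekeeping) genes
    for RT-qPCR normalisation. Screens candidate genes from RNA-seq abundance
    matrices (TPM) by a mean-expression floor and least-variation ranking with
    dual with/without-stage rankings, top-N overlap and homeolog selection;
    performs technical-replicate concordance filtering of Ct tables and
    amplification-efficiency estimation from dilution standard curves; ranks
    candidates with four independent stability statistics (comparative
    delta-Ct, geNorm M and pairwise-variation V, BestKeeper, NormFinder) plus
    a consensus ranking; quantifies target genes against a multi-gene
    reference set by the 2^-ddCt method; and simulates Ct tables, TPM
    matrices and dilution series with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
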