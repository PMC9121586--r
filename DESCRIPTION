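Package: bsascan
Title: Bulked-Segregant QTL-seq Scans with a Simulated F2 Cross
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the QTL-seq flavour of bulked segregant analysis for
    biparental crosses: quality filtering of pooled variant calls, per-site
    SNP-index and delta(SNP-index) statistics, sliding-window smoothing,
    depth-conditional Monte-Carlo confidence bands under the no-QTL null,
    and candidate-region calling. A forward simulator of an F2 population
    (crossover meiosis, an incompletely dominant major locus, extreme-tail
    bulking, pooled short-read allele sampling) provides ground-truthed
    inputs so every stage of the scan is testable without raw reads.
    Companion helpers cover single-marker LOD/PVE scans and comparative-Ct
    (2^-ddCt) relative-expression analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
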