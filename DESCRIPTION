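Package: peakconcord
Title: Peak-Set Concordance Benchmarking for Low-Input ChIP-seq
Version: 0.1.0
Authors@R:
    person("Iris", "Martin", email = "iris.martin@example.org",
           role = c("aut", "cre"))
Description: Tools to benchmark ChIP-seq peak calls against a trusted
    reference peak set, as used to establish operational cell-number
    limits for low-input chromatin immunoprecipitation protocols.
    Provides BED/chrom.sizes input-output and genomic interval algebra
    (sort, merge with a base-pair gap, complement, fractional-overlap
    intersection), interval-level confusion matrices with sensitivity,
    specificity and positive predictive value, location of the optimal
    input amount as the intersection of the sensitivity and specificity
    curves on a log cell-number axis, scaled metagene
    log(observed/expected) enrichment profiles with rank-sum profile
    comparison, sequencing-library accounting arithmetic (duplicate
    rates, downsampling fractions, qPCR amplification-cycle selection),
    and a synthetic-data generator with known ground truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
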