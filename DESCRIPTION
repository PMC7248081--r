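Package: cleavescan
Title: CpG-Island Methylation Inference from DNA Fragmentation Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates CpG methylation from the sequence bias of DNA
    fragmentation in whole-genome sequencing libraries. Read 5'-end
    coordinates are converted into per-dinucleotide cleavage rates
    normalized by the local (200 bp) genomic background, with CpG split
    into methylated, unmethylated and undetermined classes using
    bisulfite-derived methylation maps. CpG islands are scored by their
    island-restricted CpG cleavage rate, island-score vectors are
    assembled into a sample-by-island feature matrix, and tumor versus
    normal status is classified with a linear support vector machine
    evaluated by balanced jack-knife resampling. A fragmentation
    simulator with known per-class break weights provides ground truth
    for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    e1071,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
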