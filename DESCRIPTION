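Package: cenkmer
Title: Reference-Free K-mer Enrichment and Interval Analytics for
    Centromeric CUT&RUN
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@cenkmer.org",
           role = c("aut", "cre"))
Description: Tools for analysing chromatin profiling data over centromeric
    and pericentromeric repeats without relying on unique alignment.
    Counts canonical 51-mers per replicate, normalises by total base
    counts, pools salt fractions and calls k-mers enriched over an
    averaged IgG control; maps enriched k-mers back to a genome by exact
    match and attributes sites to satellite annotation classes; provides
    replicate-consensus peak merging, overlap summaries, peak
    categorisation, signal matrices, feature distributions and the
    relative-distance statistic; quantifies radial ring intensity
    profiles and shape metrics of immunofluorescence foci; and computes
    protein-panel abundance statistics. Includes simulators for toy
    repeat genomes, paired-end reads with planted enrichment, and
    nucleus images with known radial ground truth, so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
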