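Package: shmscan
Title: Somatic Hypermutation Hotspot Detection from Active-Mark ChIP-seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of somatic-hypermutation (SHM) hotspots in
    5' gene-regulatory regions using reads from an active-histone-mark
    (e.g. H3K4me3) ChIP-seq experiment. Clonal reads are collapsed, a
    per-sequencing-cycle error profile is estimated from all uniquely aligned
    reads, and each covered promoter position is scored with the exact
    Poisson-Binomial tail probability of its mismatch count under that
    profile. Candidate variants are filtered against a known-polymorphism
    set and by allele ratio and base-quality criteria, aggregated per gene
    over 4-kb windows centred on transcription start sites, tested for
    clustering with a Poisson model, and tested for enrichment of AID
    target motifs (RGYW/WRCY and WA/TW) with permutation z-scores. A
    synthetic-experiment generator produces complete self-consistent inputs
    (genome, gene models, known variants, aligned reads) with planted
    variants and hotspots for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    Rcpp,
    Rsamtools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomeInfoDb,
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
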