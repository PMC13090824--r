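Package: ispcr
Title: In Silico PCR: Targeted Amplicon Assembly from Raw Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the exact genomic region spanned by a pair of PCR
    primers directly from raw shotgun sequencing reads (in silico PCR).
    Canonical k-mers are counted from FASTQ/FASTA input into a 2-bit-encoded
    hash table; user primers are trimmed to their 3' ends, expanded over IUPAC
    degeneracies and a mismatch neighborhood, and intersected with the table
    to form start and end k-mer seed sets; a bounded de Bruijn graph traversal
    then emits every unique path from a start k-mer to an end k-mer within the
    expected product-length window. Also provides incremental k-mer spectrum
    histograms over growing read subsets, a synthetic genome and read
    simulator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
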