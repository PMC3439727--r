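Package: matefill
Title: Seed-and-Extend Local Assembly of the Insert Between Paired Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A local assembler for short paired-end sequencing reads. Starting
    from one read of a pair (the seed), the contig is repeatedly extended
    through fingerprint-indexed suffix-prefix overlaps and a
    representation-rate policed consensus until the seed's mate is located,
    yielding certified contigs that reconstruct the insert between the two
    mates. Includes a paired-read simulator with truth coordinates, an
    exact-locus Smith-Waterman validation of contigs, and confusion and
    genome-coverage summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
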