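Package: burnish
Title: Genome Assembly Polishing and Variant Detection from Short-Read
    Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Polishes draft genome assemblies and calls variants against a
    reference using aligned short reads. Builds quality-weighted pileups to
    confirm or correct single bases, left-normalizes and calls small indels,
    scans for read-alignment discontiguities indicating mis-assemblies or
    large indels, locally reassembles suspicious regions and captured gaps
    with a pruned De Bruijn graph, and flags large collapsed repeats from
    coverage. Emits a corrected FASTA, VCF (including assembled large-event
    sequences), a tabular changes ledger, genome-browser tracks, and a text
    summary. Includes a deterministic synthetic-fixture generator (genomes,
    mutated drafts with truth ledgers, simulated paired reads and
    truth-projected alignments) so the full pipeline is testable without
    external data or an aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    data.table
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
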