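Package: primercov
Title: In Silico Coverage Evaluation of PCR Primers and Primer Pairs
Version: 0.1.0
Authors@R:
    person("primercov", "developers", email = "devnull@example.org", role = c("aut", "cre"))
Description: Evaluates single primers and primer pairs in silico against any
    nucleotide sequence database. Primers may contain IUPAC degenerate bases
    and are located with a substitution-mismatch budget; primer pairs
    additionally support amplicon length bounds. Coverage is reported per
    sequence, per taxon at a chosen taxonomic level, or per clade (every
    lineage prefix), together with mean start/end positions and mean amplicon
    length. Includes readers and writers for mothur-style oligos files, FASTA
    and semicolon-delimited taxonomy tables, a deterministic synthetic-data
    generator with planted primer sites and exact ground truth, a batched
    accession download module with injectable transport, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
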