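# Small in-code builders shared across test files.

toy_targets <- function(seqs) {
  data.frame(id = names(seqs), sequence = unname(unlist(seqs)),
             stringsAsFactors = FALSE)
}

toy_lineages <- function(lins, level_names) {
  attr(lins, "level_names") <- level_names
  lins
}

# A small reusable fixture spec: 2 phyla x 2 species x 2 sequences, one
# forward and one reverse primer plus one pair, with a configurable number
# of substitutions injected into every planted copy.
small_spec <- function(seed, inject = 0L) {
  fixture_spec(
    level_names = c("phylum", "species"), taxa = c(2L, 2L),
    seqs_per_taxon = 2L, seq_length = 150L, gc = 0.5,
    primers = list(
      list(name = "pf", role = "forward", sequence = "ACGTTGCATCGATTGACA",
           taxa = 1:2, mismatches = inject),
      list(name = "pr", role = "reverse", sequence = "TGCACTGATGCTAGCTTG",
           taxa = 2:3, mismatches = inject)),
    pairs = list(
      list(name = "pp", fwd = "GATTCGAGCTAGGCATCC", rev = "CCATGGATCGTTAGCAGT",
           taxa = c(1L, 3L), spacing = 30L, mismatches = inject)),
    screen_mismatches = 2L, seed = seed)
}

fixture_db <- function(fix) {
  fa <- tempfile(fileext = ".fasta")
  tx <- tempfile(fileext = ".tax")
  writeLines(fix$fasta, fa)
  writeLines(fix$taxonomy, tx)
  list(targets = read_fasta(fa),
       lineages = read_taxonomy(tx, fix$truth$level_names))
}
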