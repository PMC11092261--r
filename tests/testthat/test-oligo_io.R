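test_that("parse_oligos maps roles, names and degenerate sequences", {
  p <- parse_oligos(c("forward ACGT p1",
                      "reverse  TTKG",
                      "primer AAGG TTCC pA",
                      "# a comment",
                      "",
                      "519r CAGCMGCCGCGGTAA s4",
                      "GGACTACHVGGGTWTCTAAT bare"))
  expect_equal(p$role, c("forward", "reverse", "pair", "unknown", "unknown"))
  expect_equal(p$name, c("p1", "primer_2", "pA", "s4", "bare"))
  expect_equal(p$sequence[1], "ACGT")
  expect_equal(p$fwd_sequence[3], "AAGG")
  expect_equal(p$rev_sequence[3], "TTCC")
  expect_equal(p$sequence[4], "CAGCMGCCGCGGTAA")
  # order preserved, auto-name counts in file order
  expect_equal(p$sequence[2], "TTKG")
})

test_that("parse_oligos rejects malformed lines with located errors", {
  expect_error(parse_oligos("forward ACXT p2"), "non-IUPAC character 'X'")
  expect_error(parse_oligos(c("forward ACGT", "primer AAGG")), "line 2")
  expect_error(parse_oligos("forward A C G T"), "needs 2-3 fields")
  expect_error(parse_oligos("fnord ??? x"), "cannot parse")
  expect_warning(p <- parse_oligos(c("barcode ACGT s", "forward ACGT")),
                 "barcode")
  expect_equal(nrow(p), 1L)
})

test_that("parse_oligos o serialize_oligos is the identity", {
  p <- parse_oligos(c("forward ACGTR p1", "reverse TTKG",
                      "primer AAGG TTCC pA", "CAGCMG u1"))
  expect_equal(parse_oligos(serialize_oligos(p)), p)
})

test_that("read_fasta concatenates, tokenizes headers and validates", {
  f <- withr::local_tempfile(lines = c(">s1 some description", "AC", "gt",
                                       ">s2", "AAAA"))
  db <- read_fasta(f)
  expect_equal(db$id, c("s1", "s2"))
  expect_equal(db$sequence, c("ACGT", "AAAA"))

  dup <- withr::local_tempfile(lines = c(">s1", "AAAA", ">s1", "CCCC"))
  expect_error(read_fasta(dup), "duplicate.*s1")
  empty <- withr::local_tempfile(lines = character(0))
  expect_error(read_fasta(empty), "no FASTA records")
})

test_that("read_taxonomy parses lineages and is total over its file", {
  f <- withr::local_tempfile(lines = c("s1\tBacteria;Firmicutes;",
                                       "s2\tBacteria;Proteobacteria"))
  lin <- read_taxonomy(f, c("domain", "phylum"))
  expect_equal(lin$s1, c("Bacteria", "Firmicutes"))
  expect_equal(lin$s2, c("Bacteria", "Proteobacteria"))
  expect_equal(attr(lin, "level_names"), c("domain", "phylum"))

  bad <- withr::local_tempfile(lines = c("s1\tBacteria;Firmicutes",
                                         "s2\tBacteria"))
  expect_error(read_taxonomy(bad, c("domain", "phylum")), "line 2")
  nodepth <- withr::local_tempfile(lines = "s1\tBacteria;;Firmicutes")
  expect_error(read_taxonomy(nodepth, c("d", "p", "c")), "line 1")
  empty <- withr::local_tempfile(lines = character(0))
  expect_length(read_taxonomy(empty, c("domain", "phylum")), 0L)
})

test_that("write_coverage_table formats two decimals and empty fields", {
  rows <- data.frame(primer_name = c("p1", "pairX"), n_groups = c(4L, 3L),
                     n_covered = c(2L, 3L), coverage_pct = c(50, 100),
                     mean_start = c(10.5, 7), mean_end = c(30.5, 120),
                     mean_amplicon_length = c(NA, 120))
  f <- withr::local_tempfile()
  write_coverage_table(rows, f)
  lines <- readLines(f)
  expect_equal(lines[2], "p1\t4\t2\t50.00\t10.50\t30.50\t")
  expect_equal(lines[3], "pairX\t3\t3\t100.00\t7.00\t120.00\t120.00")
  write_coverage_table(rows[0, ], f)
  expect_length(readLines(f), 1L)  # header only
})

test_that("write_amplicon_fasta round-trips through read_fasta", {
  hits <- data.frame(target_id = c("s1", "s1", "s2"),
                     start = c(2L, 8L, 0L), end = c(6L, 12L, 4L),
                     matched_seq = c("ACGT", "GGCC", "TTAA"))
  f <- withr::local_tempfile()
  write_amplicon_fasta(hits, f)
  back <- read_fasta(f)
  # 1-based inclusive coordinates in headers; input order preserved
  expect_equal(back$id, c("s1|3-6", "s1|9-12", "s2|1-4"))
  expect_equal(back$sequence, hits$matched_seq)

  write_amplicon_fasta(hits[0, ], f)
  expect_identical(file.size(f), 0)
})
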