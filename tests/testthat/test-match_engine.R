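test_that("iupac_class expands codes and rejects unknowns", {
  expect_setequal(iupac_class("R"), c("A", "G"))
  expect_setequal(iupac_class("N"), c("A", "C", "G", "T"))
  expect_setequal(iupac_class("B"), c("C", "G", "T"))
  expect_setequal(iupac_class("a"), "A")
  expect_error(iupac_class("X"), "unknown IUPAC")
})

test_that("reverse_complement is IUPAC-aware and an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAR"), "YTT")
  expect_equal(reverse_complement("NGA"), "TCN")
  expect_error(reverse_complement("ACXT"), "invalid IUPAC")
  set.seed(11)
  for (i in 1:25) {
    s <- random_iupac_primer(sample(1:30, 1), 0.4)
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("find_primer_hits matches the spec's worked examples", {
  h <- find_primer_hits("ACGT", "TTACGTTT", 0)
  expect_equal(h[, c("start", "end", "mismatches")],
               data.frame(start = 2L, end = 6L, mismatches = 0L))
  expect_equal(h$matched_seq, "ACGT")

  h <- find_primer_hits("AYG", "TATGA", 0)  # Y = {C,T} accepts T
  expect_equal(h$start, 1L)
  expect_equal(h$end, 4L)

  h <- find_primer_hits("AAAA", "CCAATACC", 1)
  expect_equal(h$start, 2L)
  expect_equal(h$mismatches, 1L)
  expect_equal(nrow(h), 1L)

  # overlapping hits are all reported, ascending
  h <- find_primer_hits("AA", "AAAA", 0)
  expect_equal(h$start, 0:2)

  expect_equal(nrow(find_primer_hits("ACGTACGT", "ACG", 0)), 0L)
})

test_that("a degenerate target character never matches by set intersection", {
  # target N vs primer R={A,G}: one mismatch, not a match
  expect_equal(nrow(find_primer_hits("R", "N", 0)), 0L)
  expect_equal(find_primer_hits("R", "N", 1)$mismatches, 1L)
  # even primer N does not accept target N
  expect_equal(nrow(find_primer_hits("N", "N", 0)), 0L)
})

test_that("engine agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    primer <- random_iupac_primer(sample(4:25, 1), runif(1, 0, 0.5))
    target <- random_target(sample(20:200, 1))
    mm <- sample(0:3, 1)
    got <- find_primer_hits(primer, target, mm)
    want <- oracle_hits(primer, target, mm)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("hit sets are monotone in the mismatch budget", {
  set.seed(202)
  for (i in 1:50) {
    primer <- random_iupac_primer(sample(4:15, 1), runif(1, 0, 0.5))
    target <- random_target(sample(30:150, 1))
    prev <- integer(0)
    for (mm in 0:3) {
      cur <- find_primer_hits(primer, target, mm)$start
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("find_amplicons places pairs and applies length bounds", {
  a <- find_amplicons("AAA", "TTT", "GGAAACCCCTTTGG")
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 2L)
  expect_equal(a$end, 12L)
  expect_equal(a$length, 10L)
  expect_equal(a$amplicon_seq, "AAACCCCTTT")

  expect_equal(nrow(find_amplicons("AAA", "TTT", "GGAAACCCCTTTGG",
                                   min_len = 11)), 0L)

  # brute-force enumeration: 2 fwd x 2 rev placements, all valid
  a <- find_amplicons("AA", "TT", "AAGAAGTTCTT")
  expect_equal(nrow(a), 4L)
  expect_equal(a$start[1], 0L)   # representative: leftmost ...
  expect_equal(a$length[1], 8L)  # ... then shortest
  expect_equal(a[, c("start", "end")],
               data.frame(start = c(0L, 0L, 3L, 3L), end = c(8L, 11L, 8L, 11L)))

  # footprints may not overlap
  expect_equal(nrow(find_amplicons("AAG", "AGT", "AAGTT")), 0L)
})

test_that("rc_reverse searches the reverse complement of the reverse primer", {
  # reverse primer written as its annealing strand: rc("CCCTT") = "AAGGG"
  target <- "GGAAACCCCAAGGGGG"
  expect_equal(nrow(find_amplicons("AAA", "CCCTT", target)), 0L)
  a <- find_amplicons("AAA", "CCCTT", target, rc_reverse = TRUE)
  expect_equal(a$length, 12L)
})

test_that("amplicon invariants hold on random instances", {
  set.seed(303)
  n_amp <- 0L
  for (i in 1:60) {
    fwd <- random_iupac_primer(sample(3:6, 1), 0.2)
    rev <- random_iupac_primer(sample(3:6, 1), 0.2)
    target <- random_target(sample(40:120, 1))
    a <- find_amplicons(fwd, rev, target, max_mismatches = sample(0:2, 1))
    if (nrow(a) == 0L) next
    n_amp <- n_amp + nrow(a)
    expect_true(all(a$fwd_end <= a$rev_start))
    expect_equal(a$end - a$start, a$length)
    expect_equal(nchar(a$amplicon_seq), a$length)
    expect_true(!is.unsorted(a$start))
  }
  expect_gt(n_amp, 0L)  # the case generator actually produced amplicons
})

test_that("planted sites are recovered at their exact offsets", {
  set.seed(404)
  for (i in 1:20) {
    primer <- random_iupac_primer(15, 0.2)
    site <- paste(vapply(strsplit(primer, "")[[1]],
                         function(ch) sample(iupac_class(ch), 1), ""),
                  collapse = "")
    offset <- sample(0:80, 1)
    target <- paste0(random_target(offset), site, random_target(30))
    h <- find_primer_hits(primer, target, 0)
    expect_true(offset %in% h$start)
    expect_equal(h$mismatches[h$start == offset], 0L)
  }
})
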