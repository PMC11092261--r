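# Planted-design fixtures used throughout: primer "GATTACAGATTACA" present
# verbatim in chosen sequences, never elsewhere (backgrounds are G/C only).
P <- "GATTACAGATTACA"
plant_db <- function(hit_ids, n = 4L) {
  ids <- paste0("s", seq_len(n))
  seqs <- vapply(ids, function(id) {
    bg <- strrep("GC", 30)
    if (id %in% hit_ids) paste0(substr(bg, 1, 10), P, substr(bg, 11, 60))
    else bg
  }, character(1))
  toy_targets(as.list(seqs))
}

test_that("analyze_ip computes sequence-mode and species-mode coverage", {
  db <- plant_db(c("s1", "s2"))
  primers <- parse_oligos(paste("forward", P, "p1"))
  res <- analyze_ip(primers, db)
  expect_equal(res$coverage$coverage_pct, 50)
  expect_equal(res$coverage$n_groups, 4L)
  expect_equal(res$coverage$mean_start, 11)  # planted after 10 bg nt, 1-based
  expect_equal(res$coverage$mean_end, 10 + nchar(P))
  expect_true(is.na(res$coverage$mean_amplicon_length))

  # the 2 hit sequences are the only members of 1 of 3 species
  lin <- toy_lineages(list(s1 = c("X", "sp1"), s2 = c("X", "sp1"),
                           s3 = c("X", "sp2"), s4 = c("Y", "sp3")),
                      c("phylum", "species"))
  res <- analyze_ip(primers, db, lin,
                    run_config(mode = "level", level = "species"))
  expect_equal(res$coverage$n_groups, 3L)
  expect_equal(res$coverage$coverage_pct, 100 / 3)

  dead <- parse_oligos("forward AAAAAAAAAA pdead")
  res <- analyze_ip(dead, db)
  expect_equal(res$coverage$coverage_pct, 0)
  expect_equal(nrow(res$details$pdead$hits), 0L)
})

test_that("unknown-role primers count hits in either orientation", {
  # s1 carries the primer as written, s2 its reverse complement
  db <- toy_targets(list(s1 = paste0("GCGCGC", P, "GCGCGC"),
                         s2 = paste0("GCGCGC", reverse_complement(P), "GCGCGC"),
                         s3 = strrep("GC", 20)))
  unk <- parse_oligos(paste(P, "u1"))
  expect_equal(unk$role, "unknown")
  res <- analyze_ip(unk, db)
  expect_equal(res$coverage$coverage_pct, 100 * 2 / 3)
  fwd <- parse_oligos(paste("forward", P, "f1"))
  expect_equal(analyze_ip(fwd, db)$coverage$coverage_pct, 100 / 3)
})

test_that("analyze_pp requires both hits and honours length bounds", {
  fwd <- "GATTACAGAT"; rev <- "CATCATCATT"
  amp_ids <- c("s1", "s2", "s3")
  ids <- paste0("s", 1:5)
  seqs <- vapply(ids, function(id) {
    bg <- strrep("GC", 40)
    if (id %in% amp_ids) {
      paste0(substr(bg, 1, 8), fwd, strrep("G", 80), rev, substr(bg, 9, 80))
    } else bg
  }, character(1))
  db <- toy_targets(as.list(seqs))
  pairs <- parse_oligos(paste("primer", fwd, rev, "pp1"))
  amp_len <- nchar(fwd) + 80 + nchar(rev)

  res <- analyze_pp(pairs, db, config = run_config(min_len = 50, max_len = 200))
  expect_equal(res$coverage$coverage_pct, 60)
  expect_equal(res$coverage$mean_amplicon_length, amp_len)

  res80 <- analyze_pp(pairs, db, config = run_config(max_len = 80))
  expect_equal(res80$coverage$coverage_pct, 0)

  unbounded <- analyze_pp(pairs, db)
  expect_equal(unbounded$coverage$coverage_pct, 60)  # no-op bounds

  expect_error(analyze_pp(parse_oligos("forward ACGT x"), db), "pair")
  expect_error(analyze_ip(pairs, db), "single")
})

test_that("classify_domains implements the four-way call", {
  b <- data.frame(primer_name = c("p1", "p2", "p3", "p4"),
                  coverage_pct = c(30, 0, 12.5, 0))
  a <- data.frame(primer_name = c("p4", "p3", "p2", "p1"),
                  coverage_pct = c(0, 80, 40, 0))
  calls <- classify_domains(b, a)
  expect_equal(calls$call, c("bacteria", "archaea", "universal", "none"))
  expect_equal(calls$archaeal_cov_pct, c(0, 40, 80, 0))
  expect_equal(sum(domain_counts(calls)), 4L)
  expect_error(classify_domains(b, a[-1, ]), "only one coverage table")
})

test_that("build_candidate_pairs crosses eligible primers at >= threshold", {
  rows <- data.frame(
    primer_name = paste0("p", 1:7),
    role = c("forward", "forward", "forward", "reverse", "reverse",
             "forward", "reverse"),
    coverage_pct = c(90, 80, 75, 99, 76, 74.99, 10),
    sequence = strrep(c("A", "C", "G", "T", "W", "K", "M"), 10))
  pairs <- build_candidate_pairs(rows, 75)
  expect_equal(nrow(pairs), 6L)  # 3 eligible forward x 2 eligible reverse
  expect_true(all(pairs$role == "pair"))
  expect_true("p1-p4" %in% pairs$name)
  expect_false(any(grepl("p6", pairs$name)))  # 74.99 < 75, unrounded

  # unknown primers are eligible on both sides
  rows$role[1] <- "unknown"
  pairs <- build_candidate_pairs(rows, 75)
  expect_equal(nrow(pairs), 3L * 3L)  # p1 now eligible on both sides
  expect_true("p1-p1" %in% pairs$name)

  expect_warning(none <- build_candidate_pairs(rows[rows$role == "forward", ]),
                 "no eligible reverse")
  expect_equal(nrow(none), 0L)
})

test_that("pair coverage never exceeds either single-primer coverage", {
  for (seed in c(5, 6)) {
    fix <- generate_fixture(small_spec(seed))
    db <- fixture_db(fix)
    pair <- fix$primers[fix$primers$role == "pair", ]
    singles <- primercov:::primer_df(
      name = c("f", "r"), role = c("forward", "reverse"),
      sequence = c(pair$fwd_sequence, pair$rev_sequence),
      fwd_sequence = NA_character_, rev_sequence = NA_character_)
    for (cfg in list(run_config(),
                     run_config(mode = "level", level = "species"))) {
      cov_pp <- analyze_pp(pair, db$targets, db$lineages, cfg)$coverage$coverage_pct
      cov_ip <- analyze_ip(singles, db$targets, db$lineages, cfg)$coverage$coverage_pct
      expect_lte(cov_pp, min(cov_ip) + 1e-9)
    }
  }
})

test_that("run_case_study classifies domains and ranks candidate pairs", {
  # two bacteria-only primers, one archaea-only, one universal, one dead
  mk <- function(seed, planted) {
    spec <- fixture_spec(
      level_names = c("phylum", "species"), taxa = c(2L, 2L),
      seqs_per_taxon = 2L, seq_length = 200L,
      primers = list(
        list(name = "b_f", role = "forward", sequence = "ACGTTGCATCGATTGACA",
             taxa = planted$b_f, mismatches = 0L),
        list(name = "b_r", role = "reverse", sequence = "TGCACTGATGCTAGCTTG",
             taxa = planted$b_r, mismatches = 0L),
        list(name = "a_f", role = "forward", sequence = "GATTCGAGCTAGGCATCC",
             taxa = planted$a_f, mismatches = 0L),
        list(name = "u_r", role = "reverse", sequence = "CCATGGATCGTTAGCAGT",
             taxa = planted$u_r, mismatches = 0L),
        list(name = "dead", role = "forward", sequence = "TTGACCGGTTAACCGGTT",
             taxa = integer(0), mismatches = 0L)),
      seed = seed)
    fixture_db(generate_fixture(spec))
  }
  bact <- mk(21, list(b_f = 1:4, b_r = 1:4, a_f = integer(0), u_r = 1:4))
  arch <- mk(22, list(b_f = integer(0), b_r = integer(0), a_f = 1:4, u_r = 1:4))
  primers <- parse_oligos(c("forward ACGTTGCATCGATTGACA b_f",
                            "reverse TGCACTGATGCTAGCTTG b_r",
                            "forward GATTCGAGCTAGGCATCC a_f",
                            "reverse CCATGGATCGTTAGCAGT u_r",
                            "forward TTGACCGGTTAACCGGTT dead"))
  cfg <- run_config(mode = "level", level = "species")
  res <- run_case_study(primers, bact$targets, bact$lineages,
                        arch$targets, arch$lineages, cfg)
  expect_equal(unname(res$domain_counts), c(2L, 1L, 1L, 1L))
  expect_equal(sum(res$domain_counts), nrow(primers))
  calls <- res$domain_calls
  expect_equal(calls$call[calls$primer_name == "u_r"], "universal")
  expect_equal(calls$call[calls$primer_name == "dead"], "none")
  # bacterial pairs: {b_f} x {b_r, u_r}; planted order makes both amplify
  expect_setequal(res$pairs$bacteria$primer_name, c("b_f-b_r", "b_f-u_r"))
  expect_true(!is.unsorted(rev(res$pairs$bacteria$coverage_pct)))
  # archaeal pairs: {a_f} x {u_r}
  expect_equal(res$pairs$archaea$primer_name, "a_f-u_r")
  expect_equal(res$pairs$archaea$coverage_pct, 100)
})

test_that("no eligible primers yields empty pair tables, not an error", {
  fix <- generate_fixture(small_spec(31))
  db <- fixture_db(fix)
  primers <- parse_oligos("forward TTGACCGGTTAACCGGTT dead")
  res <- run_case_study(primers, db$targets, db$lineages,
                        db$targets, db$lineages,
                        run_config(mode = "level", level = "species"))
  expect_null(res$pairs$bacteria)
  expect_null(res$pairs$archaea)
  expect_equal(unname(res$domain_counts["none"]), 1L)
})
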