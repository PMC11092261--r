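# Deterministic synthetic fixtures: oligos + FASTA + taxonomy triples with
# primer sites planted at known offsets, plus an exact ground-truth record.
# Backgrounds are screened for accidental matches at the screening mismatch
# budget and regenerated on collision, so the recorded ground truth is exact,
# not probabilistic. Everything is a pure function of the seed.

local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Describe a synthetic fixture
#'
#' @param level_names Taxonomic level names, outermost first.
#' @param taxa Either an integer vector of branching factors per level
#'   (e.g. `c(2, 3)`: 2 top-level taxa with 3 subtaxa each) or a list of
#'   explicit terminal lineages (character vectors, one name per level).
#' @param seqs_per_taxon Sequences generated per terminal taxon.
#' @param seq_length Length of every generated sequence.
#' @param gc GC fraction of the background composition.
#' @param primers List of planted single primers:
#'   `list(name=, role=("forward"|"reverse"|"unknown"), sequence=, taxa=<indices
#'   of terminal taxa, possibly empty>, mismatches=<substitutions injected into
#'   every planted copy>)`. Primers with empty `taxa` appear in the oligos
#'   output but are planted nowhere (guaranteed 0% coverage).
#' @param pairs List of planted pairs: `list(name=, fwd=, rev=, taxa=,
#'   spacing=<background nt between the footprints>, mismatches=)`; the
#'   injected substitutions apply to each footprint.
#' @param screen_mismatches Budget at which backgrounds are screened for
#'   accidental hits; ground truth is exact for any analysis budget up to
#'   this value.
#' @param seed Integer seed; fully determines the fixture.
#' @return A validated spec object for [generate_fixture()].
#' @export
fixture_spec <- function(level_names = c("phylum", "species"),
                         taxa = c(2, 3), seqs_per_taxon = 2L,
                         seq_length = 150L, gc = 0.5,
                         primers = list(), pairs = list(),
                         screen_mismatches = 2L, seed = 1L) {
  stopifnot(length(level_names) >= 1L, seqs_per_taxon >= 1L, seq_length >= 20L,
            gc > 0, gc < 1, screen_mismatches >= 0L)
  terminals <- if (is.list(taxa)) {
    if (!all(vapply(taxa, length, integer(1)) == length(level_names))) {
      stop("each explicit lineage must have one name per level", call. = FALSE)
    }
    taxa
  } else {
    stopifnot(length(taxa) == length(level_names), all(taxa >= 1L))
    lins <- list(character(0))
    for (l in seq_along(taxa)) {
      lins <- unlist(lapply(lins, function(prefix) {
        lapply(seq_len(taxa[l]), function(j) {
          nm <- if (l == 1L) paste0("t", j) else paste0(prefix[l - 1L], "_", j)
          c(prefix, nm)
        })
      }), recursive = FALSE)
    }
    lins
  }
  n_term <- length(terminals)
  check_site <- function(p, seqs, kind) {
    for (s in seqs) {
      if (!is_iupac(s)) stop(kind, " '", p$name, "': invalid sequence", call. = FALSE)
      k <- p$mismatches %||% 0L
      n_mut <- sum(vapply(strsplit(toupper(s), "")[[1]],
                          function(ch) length(IUPAC_CODES[[ch]]) < 4L, logical(1)))
      if (k > n_mut) {
        stop(kind, " '", p$name, "': cannot inject ", k, " mismatches",
             call. = FALSE)
      }
      if (nchar(s) > seq_length - 10L) {
        stop(kind, " '", p$name, "': planted site longer than sequence",
             call. = FALSE)
      }
    }
    if (length(p$taxa) && (any(p$taxa < 1L) || any(p$taxa > n_term))) {
      stop(kind, " '", p$name, "': taxa indices out of range", call. = FALSE)
    }
  }
  for (p in primers) {
    stopifnot(!is.null(p$name), p$role %in% c("forward", "reverse", "unknown"))
    check_site(p, p$sequence, "primer")
  }
  for (p in pairs) {
    stopifnot(!is.null(p$name), !is.null(p$spacing), p$spacing >= 0L)
    check_site(p, c(p$fwd, p$rev), "pair")
  }
  structure(list(level_names = level_names, terminals = terminals,
                 seqs_per_taxon = as.integer(seqs_per_taxon),
                 seq_length = as.integer(seq_length), gc = gc,
                 primers = primers, pairs = pairs,
                 screen_mismatches = as.integer(screen_mismatches),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Realize a degenerate primer as a concrete site and inject exactly k
# substitutions, each outside the primer's IUPAC class at that position (so
# the planted copy has exactly k mismatches under the engine's semantics).
realize_site <- function(primer_seq, k) {
  classes <- lapply(strsplit(toupper(primer_seq), "")[[1]],
                    function(ch) IUPAC_CODES[[ch]])
  site <- vapply(classes, function(cl)
    if (length(cl) == 1L) cl else sample(cl, 1L), character(1))
  if (k > 0L) {
    eligible <- which(vapply(classes, length, integer(1)) < 4L)
    pos <- if (length(eligible) == 1L) eligible else sample(eligible, k)
    pos <- pos[seq_len(k)]
    for (i in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), classes[[i]])
      site[i] <- if (length(alt) == 1L) alt else sample(alt, 1L)
    }
  }
  paste(site, collapse = "")
}

random_background <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Introduce exactly k substitutions into a sequence
#'
#' @param site_seq A/C/G/T string.
#' @param k_substitutions Number of positions to change; each changed
#'   position gets a different base, so the Hamming distance to the input is
#'   exactly `k_substitutions`.
#' @param seed Integer seed (position and base choices are deterministic
#'   given the seed; the caller's RNG state is untouched).
#' @return The mutated sequence.
#' @export
mutate_site <- function(site_seq, k_substitutions, seed = 1L) {
  n <- nchar(site_seq)
  if (k_substitutions > n) stop("k exceeds site length", call. = FALSE)
  if (k_substitutions == 0L) return(site_seq)
  local_seed(seed, {
    chars <- strsplit(site_seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(n, k_substitutions)
    for (i in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), chars[i])
      chars[i] <- sample(alt, 1L)
    }
    paste(chars, collapse = "")
  })
}

# The list of (search string -> primer entry) the screener must check:
# singles as written, the reverse complement of unknown-role singles, and
# both components of pairs (as searched, i.e. as written).
screen_strings <- function(spec) {
  out <- list()
  add <- function(s, label) out[[length(out) + 1L]] <<- list(seq = toupper(s), label = label)
  for (p in spec$primers) {
    add(p$sequence, p$name)
    if (p$role == "unknown") add(reverse_complement(p$sequence),
                                 paste0(p$name, ":rc"))
  }
  for (p in spec$pairs) {
    add(p$fwd, paste0(p$name, ":fwd"))
    add(p$rev, paste0(p$name, ":rev"))
  }
  out
}

# Assemble one sequence with its planted sites; retry on screening collision.
build_sequence <- function(spec, singles, pairs, screens, id) {
  for (attempt in seq_len(500L)) {
    # layout: sites in spec order, left to right, random gaps
    sites <- list()  # each: list(label, start, text, k, entry)
    cursor <- sample(0:8, 1L)
    for (p in singles) {
      gap <- sample(4:12, 1L)
      start <- cursor + gap
      text <- realize_site(p$sequence, p$mismatches %||% 0L)
      sites[[length(sites) + 1L]] <- list(kind = "single", entry = p,
                                          start = start, text = text)
      cursor <- start + nchar(text)
    }
    for (p in pairs) {
      gap <- sample(4:12, 1L)
      start <- cursor + gap
      k <- p$mismatches %||% 0L
      ftext <- realize_site(p$fwd, k)
      spacer <- random_background(p$spacing, spec$gc)
      rtext <- realize_site(p$rev, k)
      text <- paste0(ftext, spacer, rtext)
      sites[[length(sites) + 1L]] <- list(kind = "pair", entry = p,
                                          start = start, text = text,
                                          flen = nchar(ftext), rlen = nchar(rtext))
      cursor <- start + nchar(text)
    }
    if (cursor > spec$seq_length) {
      stop("planted sites do not fit in sequence length ", spec$seq_length,
           call. = FALSE)
    }
    chars <- strsplit(random_background(spec$seq_length, spec$gc), "")[[1]]
    for (s in sites) {
      idx <- s$start + seq_len(nchar(s$text))
      chars[idx] <- strsplit(s$text, "", fixed = TRUE)[[1]]
    }
    seq <- paste(chars, collapse = "")
    # expected hit offsets per search string at the screening budget
    expected <- lapply(screens, function(sc) integer(0))
    names(expected) <- vapply(screens, `[[`, character(1), "label")
    for (s in sites) {
      k <- s$entry$mismatches %||% 0L
      if (k > spec$screen_mismatches) next
      if (s$kind == "single") {
        expected[[s$entry$name]] <- c(expected[[s$entry$name]], s$start)
      } else {
        expected[[paste0(s$entry$name, ":fwd")]] <-
          c(expected[[paste0(s$entry$name, ":fwd")]], s$start)
        expected[[paste0(s$entry$name, ":rev")]] <-
          c(expected[[paste0(s$entry$name, ":rev")]],
            s$start + nchar(s$text) - s$rlen)
      }
    }
    ok <- TRUE
    for (sc in screens) {
      got <- find_primer_hits(sc$seq, seq, spec$screen_mismatches)$start
      if (!identical(sort(got), sort(unique(expected[[sc$label]])))) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      plants <- do.call(rbind, lapply(sites, function(s) {
        if (s$kind == "single") {
          data.frame(id = id, primer = s$entry$name, type = "single",
                     start = s$start, end = s$start + nchar(s$text),
                     length = nchar(s$text), k = s$entry$mismatches %||% 0L,
                     stringsAsFactors = FALSE)
        } else {
          data.frame(id = id, primer = s$entry$name, type = "pair",
                     start = s$start, end = s$start + nchar(s$text),
                     length = nchar(s$text), k = s$entry$mismatches %||% 0L,
                     stringsAsFactors = FALSE)
        }
      }))
      return(list(seq = seq, plants = plants))
    }
  }
  stop("could not generate a collision-free background for '", id,
       "' after 500 attempts; adjust the fixture spec", call. = FALSE)
}

empty_plants <- function() {
  data.frame(id = character(0), primer = character(0), type = character(0),
             start = integer(0), end = integer(0), length = integer(0),
             k = integer(0), stringsAsFactors = FALSE)
}

#' Generate a synthetic oligos/FASTA/taxonomy fixture with ground truth
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, writes `fixture.oligos`,
#'   `fixture.fasta`, `fixture.tax` and `ground_truth.json` there.
#' @return List with `oligos`, `fasta`, `taxonomy` (character vectors of
#'   file lines) and `truth`: `ids`, `lineages` (named list), `level_names`,
#'   `plants` (data.frame of planted sites: id, primer, type, 0-based
#'   half-open span, length, injected mismatches `k`) and
#'   `screen_mismatches`. Identical seeds give identical bytes.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  res <- local_seed(spec$seed, {
    screens <- screen_strings(spec)
    ids <- character(0)
    seqs <- character(0)
    lineages <- list()
    plants <- list(empty_plants())
    for (t in seq_along(spec$terminals)) {
      for (r in seq_len(spec$seqs_per_taxon)) {
        id <- sprintf("seq_t%02d_r%02d", t, r)
        singles <- Filter(function(p) t %in% p$taxa, spec$primers)
        prs <- Filter(function(p) t %in% p$taxa, spec$pairs)
        built <- build_sequence(spec, singles, prs, screens, id)
        ids <- c(ids, id)
        seqs <- c(seqs, built$seq)
        lineages[[id]] <- spec$terminals[[t]]
        if (!is.null(built$plants)) plants[[length(plants) + 1L]] <- built$plants
      }
    }
    list(ids = ids, seqs = seqs, lineages = lineages,
         plants = do.call(rbind, plants))
  })
  oligos_df <- primer_df(
    name = c(vapply(spec$primers, `[[`, character(1), "name"),
             vapply(spec$pairs, `[[`, character(1), "name")),
    role = c(vapply(spec$primers, `[[`, character(1), "role"),
             rep("pair", length(spec$pairs))),
    sequence = c(vapply(spec$primers, function(p) toupper(p$sequence), character(1)),
                 rep(NA_character_, length(spec$pairs))),
    fwd_sequence = c(rep(NA_character_, length(spec$primers)),
                     vapply(spec$pairs, function(p) toupper(p$fwd), character(1))),
    rev_sequence = c(rep(NA_character_, length(spec$primers)),
                     vapply(spec$pairs, function(p) toupper(p$rev), character(1)))
  )
  fasta <- as.vector(rbind(paste0(">", res$ids), res$seqs))
  taxonomy <- vapply(res$ids, function(id)
    paste0(id, "\t", paste(res$lineages[[id]], collapse = ";"), ";"),
    character(1), USE.NAMES = FALSE)
  truth <- list(ids = res$ids, lineages = res$lineages,
                level_names = spec$level_names, plants = res$plants,
                screen_mismatches = spec$screen_mismatches)
  out <- list(oligos = serialize_oligos(oligos_df), fasta = fasta,
              taxonomy = taxonomy, truth = truth, primers = oligos_df)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(out$oligos, file.path(dir, "fixture.oligos"))
    writeLines(out$fasta, file.path(dir, "fixture.fasta"))
    writeLines(out$taxonomy, file.path(dir, "fixture.tax"))
    jsonlite::write_json(
      list(ids = truth$ids, level_names = truth$level_names,
           lineages = truth$lineages, plants = truth$plants,
           screen_mismatches = truth$screen_mismatches),
      file.path(dir, "ground_truth.json"), digits = NA)
    out$dir <- dir
  }
  out
}

# Group enumeration for ground truth, written independently of make_groups:
# plain loops over the recorded lineages.
truth_groups <- function(truth, mode, level = NULL) {
  if (mode == "none") {
    g <- as.list(truth$ids)
    names(g) <- truth$ids
    return(g)
  }
  keys <- list()
  for (id in truth$ids) {
    lin <- truth$lineages[[id]]
    pref <- if (mode == "level") {
      k <- match(level, truth$level_names)
      paste(lin[seq_len(k)], collapse = ";")
    } else {
      vapply(seq_along(lin), function(d) paste(lin[seq_len(d)], collapse = ";"),
             character(1))
    }
    for (key in pref) keys[[key]] <- c(keys[[key]], id)
  }
  keys[sort(names(keys))]
}

#' Ground-truth coverage for a planted primer or pair
#'
#' Computed purely from the fixture's construction record (planted offsets
#' and injected mismatch counts), never by running the match engine: a
#' planted copy is recovered iff its injected mismatches fit in the budget.
#'
#' @param truth `$truth` of a [generate_fixture()] result.
#' @param primer_name Name of a planted primer or pair.
#' @param budget Analysis mismatch budget (must be `<= screen_mismatches`
#'   for the truth to be exact).
#' @param mode,level Grouping as in [make_groups()].
#' @return List `n_groups`, `n_covered`, `coverage_pct`, `mean_start`,
#'   `mean_end` (1-based reporting convention) and `mean_length`.
#' @export
fixture_truth_coverage <- function(truth, primer_name, budget,
                                   mode = c("none", "level", "clades"),
                                   level = NULL) {
  mode <- match.arg(mode)
  if (budget > truth$screen_mismatches) {
    stop("truth is only exact up to the screening budget (",
         truth$screen_mismatches, ")", call. = FALSE)
  }
  pl <- truth$plants[truth$plants$primer == primer_name &
                     truth$plants$k <= budget, , drop = FALSE]
  covered <- unique(pl$id)
  groups <- truth_groups(truth, mode, level)
  n_groups <- length(groups)
  n_covered <- 0L
  for (g in groups) if (any(g %in% covered)) n_covered <- n_covered + 1L
  list(n_groups = n_groups, n_covered = n_covered,
       coverage_pct = 100 * n_covered / n_groups,
       mean_start = if (nrow(pl)) mean(pl$start + 1) else NA_real_,
       mean_end = if (nrow(pl)) mean(pl$end) else NA_real_,
       mean_length = if (nrow(pl)) mean(pl$length) else NA_real_)
}

#' The canned "mini oral" fixture
#'
#' A small two-database scene for smoke tests and documentation: a bacterial
#' database (3 phyla / 8 species / 40 sequences) and an archaeal one
#' (1 phylum / 3 species / 9 sequences), with 5 single primers (one planted
#' across all bacterial species, one across both domains, two archaeal, one
#' planted nowhere) and 2 planted primer pairs. Fixed seed, so every call
#' reproduces identical bytes.
#'
#' @param dir Directory to write `bacteria.fasta`/`.tax`,
#'   `archaea.fasta`/`.tax` and `primers.oligos` into.
#' @return List with the file `paths` and the two [generate_fixture()]
#'   results (`bacteria`, `archaea`).
#' @export
mini_oral_fixture <- function(dir) {
  phyla <- list(Bacillota = 3L, Bacteroidota = 3L, Pseudomonadota = 2L)
  bact_terminals <- unlist(lapply(names(phyla), function(ph)
    lapply(seq_len(phyla[[ph]]), function(j)
      c(ph, sprintf("%s_sp%d", ph, j)))), recursive = FALSE)
  arch_terminals <- lapply(1:3, function(j)
    c("Methanobacteriota", sprintf("Methanobacteriota_sp%d", j)))
  # fixed primer sequences (bf1 carries a degenerate R; d1 is never planted)
  seqs <- list(bf1 = "AGRGTTTGATCCTGGCTC", br1 = "GGTTACCTTGTTACGACTT",
               af1 = "TTCCGGTTGATCCYGCCG", ar1 = "GGCCATGCACCWCCTCTC",
               d1  = "TACGGYTACCTTGTTACG")
  singles <- function(taxa_of) list(
    list(name = "bf1", role = "forward", sequence = seqs$bf1,
         taxa = taxa_of$bf1, mismatches = 0L),
    list(name = "br1", role = "reverse", sequence = seqs$br1,
         taxa = taxa_of$br1, mismatches = 0L),
    list(name = "af1", role = "forward", sequence = seqs$af1,
         taxa = taxa_of$af1, mismatches = 0L),
    list(name = "ar1", role = "unknown", sequence = seqs$ar1,
         taxa = taxa_of$ar1, mismatches = 0L),
    list(name = "d1", role = "forward", sequence = seqs$d1,
         taxa = integer(0), mismatches = 0L))
  pairs <- function(taxaB, taxaA) list(
    list(name = "pairB", fwd = "ACTCCTACGGGAGGCAGC", rev = "GGACTACHVGGGTWTCTAAT",
         taxa = taxaB, spacing = 60L, mismatches = 0L),
    list(name = "pairA", fwd = "CAGCMGCCGCGGTAATAC", rev = "CCCGCCAATTCCTTTAAG",
         taxa = taxaA, spacing = 45L, mismatches = 0L))
  spec_b <- fixture_spec(
    level_names = c("phylum", "species"), taxa = bact_terminals,
    seqs_per_taxon = 5L, seq_length = 320L, gc = 0.5,
    primers = singles(list(bf1 = 1:8, br1 = 1:8, af1 = integer(0),
                           ar1 = integer(0))),
    pairs = pairs(taxaB = 1:4, taxaA = integer(0)),
    screen_mismatches = 2L, seed = 42L)
  spec_a <- fixture_spec(
    level_names = c("phylum", "species"), taxa = arch_terminals,
    seqs_per_taxon = 3L, seq_length = 320L, gc = 0.5,
    primers = singles(list(bf1 = integer(0), br1 = 1:3, af1 = 1:3, ar1 = 1:3)),
    pairs = pairs(taxaB = integer(0), taxaA = 1:2),
    screen_mismatches = 2L, seed = 43L)
  fix_b <- generate_fixture(spec_b)
  fix_a <- generate_fixture(spec_a)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    oligos = file.path(dir, "primers.oligos"),
    bacteria_fasta = file.path(dir, "bacteria.fasta"),
    bacteria_tax = file.path(dir, "bacteria.tax"),
    archaea_fasta = file.path(dir, "archaea.fasta"),
    archaea_tax = file.path(dir, "archaea.tax"))
  writeLines(fix_b$oligos, paths$oligos)
  writeLines(fix_b$fasta, paths$bacteria_fasta)
  writeLines(fix_b$taxonomy, paths$bacteria_tax)
  writeLines(fix_a$fasta, paths$archaea_fasta)
  writeLines(fix_a$taxonomy, paths$archaea_tax)
  list(paths = paths, bacteria = fix_b, archaea = fix_a)
}
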