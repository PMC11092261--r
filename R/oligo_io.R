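# Readers/writers for all on-disk formats: mothur-style oligos primer files,
# FASTA databases, semicolon-lineage taxonomy tables, coverage tables and
# amplicon FASTA output.
#
# Coordinate convention: all *written* files use 1-based inclusive positions;
# everything in memory is 0-based half-open.

primer_df <- function(name = character(0), role = character(0),
                      sequence = character(0),
                      fwd_sequence = character(0), rev_sequence = character(0)) {
  data.frame(name = name, role = role, sequence = sequence,
             fwd_sequence = fwd_sequence, rev_sequence = rev_sequence,
             stringsAsFactors = FALSE)
}

PRIMER_ROLES <- c("forward", "reverse", "pair", "unknown")

validate_primer_seq <- function(seq, lineno) {
  bad <- invalid_iupac_positions(seq)
  if (length(bad)) {
    stop("oligos line ", lineno, ": non-IUPAC character '",
         substring(toupper(seq), bad[1], bad[1]), "' in sequence '", seq, "'",
         call. = FALSE)
  }
  toupper(seq)
}

#' Parse primer definitions in the mothur oligos format
#'
#' Recognised lines are `forward SEQ [NAME]`, `reverse SEQ [NAME]` and
#' `primer FWD REV [NAME]` (a primer pair). A line whose leading keyword is
#' not recognised but which carries a valid IUPAC sequence (either as its
#' first or second field) is kept with role `"unknown"`; `barcode` lines are
#' skipped with a warning; `#` comments and blank lines are ignored. Primers
#' without a name get `primer_<k>` in file order.
#'
#' @param text Character scalar (file content) or character vector of lines.
#' @return A data.frame with columns `name`, `role` (one of forward, reverse,
#'   pair, unknown), `sequence` (single primers; `NA` for pairs) and
#'   `fwd_sequence`/`rev_sequence` (pairs; `NA` otherwise). Sequences are
#'   stored uppercase.
#' @seealso [read_oligos()], [serialize_oligos()]
#' @examples
#' parse_oligos(c("forward ACGT p1", "primer AAGG TTCC pA"))
#' @export
parse_oligos <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  out <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "[ \t]+")[[1]]
    kw <- tolower(fields[1])
    rec <- NULL
    if (kw %in% c("forward", "reverse")) {
      if (!length(fields) %in% 2:3) {
        stop("oligos line ", i, ": '", kw, "' line needs 2-3 fields, got ",
             length(fields), call. = FALSE)
      }
      rec <- list(role = kw, sequence = validate_primer_seq(fields[2], i),
                  name = if (length(fields) == 3) fields[3] else NA_character_)
    } else if (kw == "primer") {
      if (!length(fields) %in% 3:4) {
        stop("oligos line ", i, ": 'primer' line needs 3-4 fields, got ",
             length(fields), call. = FALSE)
      }
      rec <- list(role = "pair",
                  fwd = validate_primer_seq(fields[2], i),
                  rev = validate_primer_seq(fields[3], i),
                  name = if (length(fields) == 4) fields[4] else NA_character_)
    } else if (kw == "barcode") {
      warning("oligos line ", i, ": barcode line skipped", call. = FALSE)
      next
    } else if (is_iupac(fields[1]) && length(fields) <= 2) {
      # bare "SEQ [NAME]" line
      rec <- list(role = "unknown", sequence = toupper(fields[1]),
                  name = if (length(fields) == 2) fields[2] else NA_character_)
    } else if (length(fields) %in% 2:3 && is_iupac(fields[2])) {
      # unrecognised keyword but a valid sequence in field 2
      rec <- list(role = "unknown", sequence = toupper(fields[2]),
                  name = if (length(fields) == 3) fields[3] else NA_character_)
    } else {
      stop("oligos line ", i, ": cannot parse '", line, "'", call. = FALSE)
    }
    out[[length(out) + 1L]] <- rec
  }
  res <- primer_df(
    name = vapply(out, function(r) r$name, character(1)),
    role = vapply(out, function(r) r$role, character(1)),
    sequence = vapply(out, function(r)
      if (r$role == "pair") NA_character_ else r$sequence, character(1)),
    fwd_sequence = vapply(out, function(r)
      if (r$role == "pair") r$fwd else NA_character_, character(1)),
    rev_sequence = vapply(out, function(r)
      if (r$role == "pair") r$rev else NA_character_, character(1))
  )
  auto <- is.na(res$name)
  res$name[auto] <- paste0("primer_", which(auto))
  res
}

#' @rdname parse_oligos
#' @param path Path to an oligos file.
#' @export
read_oligos <- function(path) {
  parse_oligos(readLines(path, warn = FALSE))
}

#' Serialize primer records to canonical oligos lines
#'
#' Inverse of [parse_oligos()]: `parse_oligos(serialize_oligos(p))` recovers
#' `p`. Unknown-role primers are written as bare `SEQ NAME` lines.
#'
#' @param primers Primer data.frame as returned by [parse_oligos()].
#' @return Character vector of oligos lines.
#' @export
serialize_oligos <- function(primers) {
  vapply(seq_len(nrow(primers)), function(i) {
    p <- primers[i, ]
    switch(p$role,
      forward = paste("forward", p$sequence, p$name),
      reverse = paste("reverse", p$sequence, p$name),
      pair    = paste("primer", p$fwd_sequence, p$rev_sequence, p$name),
      unknown = paste(p$sequence, p$name),
      stop("unknown primer role: ", p$role)
    )
  }, character(1))
}

#' Read a FASTA sequence database
#'
#' @param path Path to a FASTA file (plain or gzip). Record ids are the first
#'   whitespace-delimited header token; multi-line sequences are concatenated,
#'   whitespace removed, and stored uppercase. Any characters are accepted
#'   (QC flags non-ACGT later); ids must be unique and the file non-empty.
#' @return data.frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA ids in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(gsub("[ \t\r\n]", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  data.frame(id = unname(ids), sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Locate the taxonomy file that accompanies a FASTA file
#'
#' Replaces the FASTA extension with `.tax` (e.g. `db.fasta` -> `db.tax`).
#' @param fasta_path Path to the FASTA file.
#' @return The derived taxonomy path (existence is not checked).
#' @export
default_taxonomy_path <- function(fasta_path) {
  paste0(tools::file_path_sans_ext(fasta_path), ".tax")
}

#' Read a per-sequence taxonomy table
#'
#' Tab-separated, one line per sequence: `id<TAB>taxon1;taxon2;...`. A single
#' trailing semicolon is tolerated; every lineage must have exactly
#' `length(level_names)` fields. There is no header line: a first line that
#' does not parse is an error like any other.
#'
#' @param path Path to the taxonomy file.
#' @param level_names Character vector naming the taxonomic levels, outermost
#'   first (e.g. `c("phylum", "species")`).
#' @return Named list mapping sequence id to a character vector of taxon
#'   names (one per level), with `level_names` attached as an attribute.
#' @export
read_taxonomy <- function(path, level_names) {
  stopifnot(is.character(level_names), length(level_names) >= 1L)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    tab <- regexpr("\t", line, fixed = TRUE)
    if (tab < 0) {
      stop("taxonomy line ", i, ": no tab separator", call. = FALSE)
    }
    id <- trimws(substring(line, 1L, tab - 1L))
    lineage_str <- sub(";\\s*$", "", trimws(substring(line, tab + 1L)))
    taxa <- trimws(strsplit(lineage_str, ";", fixed = TRUE)[[1]])
    if (length(taxa) != length(level_names) || any(!nzchar(taxa))) {
      stop("taxonomy line ", i, " (id '", id, "'): expected ",
           length(level_names), " levels, got ", length(taxa), call. = FALSE)
    }
    if (!is.null(out[[id]])) {
      stop("taxonomy line ", i, ": duplicate id '", id, "'", call. = FALSE)
    }
    out[[id]] <- taxa
  }
  attr(out, "level_names") <- level_names
  out
}

#' Write a coverage table
#'
#' Tab-separated with header `primer_name, n_groups, n_covered, coverage_pct,
#' mean_start, mean_end, mean_amplicon_length`; floats printed with 2
#' decimals; fields that are absent (single primers' amplicon length, or
#' positional means when nothing was covered) are left empty.
#'
#' @param rows Coverage data.frame as produced by [analyze_ip()] /
#'   [analyze_pp()] (`$coverage`).
#' @param path Output path.
#' @export
write_coverage_table <- function(rows, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  header <- paste(c("primer_name", "n_groups", "n_covered", "coverage_pct",
                    "mean_start", "mean_end", "mean_amplicon_length"),
                  collapse = "\t")
  body <- if (is.null(rows) || nrow(rows) == 0L) character(0) else {
    paste(rows$primer_name, rows$n_groups, rows$n_covered,
          fmt(rows$coverage_pct), fmt(rows$mean_start), fmt(rows$mean_end),
          fmt(rows$mean_amplicon_length), sep = "\t")
  }
  writeLines(c(header, body), path)
}

#' Write matched subsequences or amplicons as FASTA
#'
#' One record per hit, header `<source_id>|<start>-<end>` with 1-based
#' inclusive coordinates (converted from the internal 0-based half-open
#' span). Input order is preserved; an empty hit table yields an empty file.
#'
#' @param hits data.frame with columns `target_id`, `start`, `end` (0-based
#'   half-open) and a sequence column (`matched_seq` or `amplicon_seq`).
#' @param path Output path.
#' @export
write_amplicon_fasta <- function(hits, path) {
  if (is.null(hits) || nrow(hits) == 0L) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(), path)
    return(invisible(path))
  }
  seq_col <- if ("amplicon_seq" %in% names(hits)) "amplicon_seq" else "matched_seq"
  set <- Biostrings::BStringSet(hits[[seq_col]])
  names(set) <- sprintf("%s|%d-%d", hits$target_id, hits$start + 1L, hits$end)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write per-group coverage
#'
#' Tab-separated table `group_key, n_members, pct_covered` (2 decimals).
#' @param groups Named list of member-id vectors (see [make_groups()]).
#' @param pct Named numeric from [per_group_coverage()].
#' @param path Output path.
#' @export
write_group_coverage <- function(groups, pct, path) {
  header <- "group_key\tn_members\tpct_covered"
  keys <- names(groups)
  body <- sprintf("%s\t%d\t%.2f", keys,
                  vapply(groups, length, integer(1)), pct[keys])
  writeLines(c(header, if (length(keys)) body), path)
}
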