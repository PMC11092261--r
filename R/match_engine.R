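# Core search engine: locate a (possibly degenerate) primer in a target
# sequence under a substitution-only mismatch budget, and enumerate
# forward/reverse placements that form valid amplicons.
#
# Semantics: a window of the target at offset i matches when the number of
# positions j with target[i+j] not in iupac_class(primer[j]) is at most the
# budget. Target characters are compared literally: a degenerate character in
# the *target* (e.g. N) is a mismatch against any primer class that does not
# contain it as a letter, so it always costs a mismatch (classes contain only
# A/C/G/T). Indels are not modelled; all coordinates are 0-based half-open.

empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0), mismatches = integer(0),
             matched_seq = character(0), stringsAsFactors = FALSE)
}

#' Find all mismatch-tolerant occurrences of a primer in a target sequence
#'
#' Slides the primer over the target and reports every offset whose window
#' has at most `max_mismatches` positions outside the primer's IUPAC classes.
#' Overlapping hits are all reported, in ascending offset order.
#'
#' @param primer_seq IUPAC primer string (searched as written; no implicit
#'   reverse complement).
#' @param target_seq Target nucleotide string.
#' @param max_mismatches Non-negative substitution budget (default 0).
#' @return data.frame with columns `start`, `end` (0-based half-open, so
#'   `end - start` equals the primer length), `mismatches` and `matched_seq`.
#' @examples
#' find_primer_hits("AYG", "TATGA", 0) # Y = C or T accepts the T
#' @export
find_primer_hits <- function(primer_seq, target_seq, max_mismatches = 0L) {
  stopifnot(length(primer_seq) == 1L, length(target_seq) == 1L)
  if (max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  primer_seq <- toupper(primer_seq)
  bad <- invalid_iupac_positions(primer_seq)
  if (!nzchar(primer_seq) || length(bad)) {
    stop("invalid primer sequence '", primer_seq, "'", call. = FALSE)
  }
  target_seq <- toupper(target_seq)
  m <- nchar(primer_seq)
  n <- nchar(target_seq)
  if (m > n) return(empty_hits())
  tcode <- utf8ToInt(target_seq)
  tcode[tcode > 256L] <- 1L  # non-ASCII can never match
  n_win <- n - m + 1L
  pch <- strsplit(primer_seq, "", fixed = TRUE)[[1]]
  mm <- integer(n_win)
  for (j in seq_len(m)) {
    mm <- mm + !.iupac_lookup[pch[j], tcode[j:(j + n_win - 1L)]]
  }
  starts <- which(mm <= max_mismatches)
  if (!length(starts)) return(empty_hits())
  data.frame(start = starts - 1L, end = starts - 1L + m,
             mismatches = mm[starts],
             matched_seq = substring(target_seq, starts, starts + m - 1L),
             stringsAsFactors = FALSE)
}

empty_amplicons <- function() {
  data.frame(fwd_start = integer(0), fwd_end = integer(0),
             rev_start = integer(0), rev_end = integer(0),
             start = integer(0), end = integer(0), length = integer(0),
             mismatches = integer(0), amplicon_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate amplicons formed by a forward/reverse primer pair
#'
#' Every combination of a forward hit `f` and a reverse hit `r` with
#' non-overlapping footprints (`f.end <= r.start`) is a candidate amplicon
#' spanning `[f.start, r.end)` — the span *includes* both primer footprints,
#' i.e. the physical PCR product. Candidates outside `[min_len, max_len]` are
#' discarded. Results are sorted by (start, length); the first row is the
#' representative used for per-sequence summaries (leftmost, then shortest —
#' the dominant short product).
#'
#' @param fwd_seq Forward primer (IUPAC, as written).
#' @param rev_seq Reverse primer. By default searched literally as written —
#'   primers must be supplied in the correct direction for amplification.
#'   With `rc_reverse = TRUE` it is IUPAC-aware reverse-complemented first.
#' @param target_seq Target nucleotide string.
#' @param max_mismatches Substitution budget applied to each primer
#'   independently.
#' @param min_len,max_len Optional bounds on the primer-inclusive amplicon
#'   length (`NULL` = unbounded).
#' @param rc_reverse Reverse-complement the reverse primer before searching.
#' @return data.frame with one row per valid amplicon: footprint coordinates
#'   (`fwd_start`..`rev_end`), span `start`/`end`, `length`, summed
#'   `mismatches` and `amplicon_seq`. Columns use 0-based half-open indices.
#' @export
find_amplicons <- function(fwd_seq, rev_seq, target_seq, max_mismatches = 0L,
                           min_len = NULL, max_len = NULL, rc_reverse = FALSE) {
  if (!is.null(min_len) && !is.null(max_len) && min_len > max_len) {
    stop("min_len must be <= max_len", call. = FALSE)
  }
  rev_search <- if (rc_reverse) reverse_complement(rev_seq) else toupper(rev_seq)
  fh <- find_primer_hits(fwd_seq, target_seq, max_mismatches)
  if (nrow(fh) == 0L) return(empty_amplicons())
  rh <- find_primer_hits(rev_search, target_seq, max_mismatches)
  if (nrow(rh) == 0L) return(empty_amplicons())
  combos <- expand.grid(fi = seq_len(nrow(fh)), ri = seq_len(nrow(rh)))
  f <- fh[combos$fi, ]
  r <- rh[combos$ri, ]
  keep <- f$end <= r$start
  len <- r$end - f$start
  if (!is.null(min_len)) keep <- keep & len >= min_len
  if (!is.null(max_len)) keep <- keep & len <= max_len
  if (!any(keep)) return(empty_amplicons())
  f <- f[keep, ]; r <- r[keep, ]; len <- len[keep]
  target_seq <- toupper(target_seq)
  out <- data.frame(fwd_start = f$start, fwd_end = f$end,
                    rev_start = r$start, rev_end = r$end,
                    start = f$start, end = r$end, length = len,
                    mismatches = f$mismatches + r$mismatches,
                    amplicon_seq = substring(target_seq, f$start + 1L, r$end),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
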