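# Sequence quality control: flag characters outside {A,C,G,T} (U from RNA,
# IUPAC ambiguity codes, gap or stray characters) and apply a keep/drop
# policy. The default is keep: flagged characters stay in the sequence and
# take part in matching as literal characters.

#' Scan one sequence for non-standard nucleotides
#'
#' @param sequence Uppercase nucleotide string.
#' @return data.frame with columns `position` (0-based) and `char`, one row
#'   per character outside `{A,C,G,T}`; zero rows for a clean sequence.
#' @examples
#' scan_sequence("ACGU") # flags U at position 3
#' @export
scan_sequence <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  data.frame(position = bad - 1L, char = chars[bad], stringsAsFactors = FALSE)
}

#' QC-scan a whole database
#'
#' @param targets data.frame from [read_fasta()].
#' @return Named list (by sequence id) of [scan_sequence()] results, with a
#'   `summary` attribute counting occurrences per offending character.
#' @export
qc_scan <- function(targets) {
  reports <- lapply(targets$sequence, scan_sequence)
  names(reports) <- targets$id
  all_chars <- unlist(lapply(reports, `[[`, "char"))
  attr(reports, "summary") <- if (length(all_chars)) table(all_chars) else table(character(0))
  reports
}

#' Apply a QC policy to flagged sequences
#'
#' `keep` retains every sequence and logs a warning line per flagged one;
#' `drop` removes sequences with at least one flagged character.
#'
#' @param targets data.frame from [read_fasta()].
#' @param reports QC reports from [qc_scan()] for the same records.
#' @param policy `"keep"` (default) or `"drop"`.
#' @return List with `targets` (the filtered data.frame) and `log` (character
#'   vector of log lines). Dropping every sequence is an error.
#' @export
apply_policy <- function(targets, reports, policy = c("keep", "drop")) {
  policy <- match.arg(policy)
  n_flag <- vapply(targets$id, function(id) nrow(reports[[id]]), integer(1))
  flagged <- targets$id[n_flag > 0L]
  log <- character(0)
  if (policy == "keep") {
    if (length(flagged)) {
      log <- sprintf("QC: sequence '%s' has %d non-ACGT character(s); kept",
                     flagged, n_flag[n_flag > 0L])
    }
    return(list(targets = targets, log = log))
  }
  kept <- targets[n_flag == 0L, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no sequences remain after QC (policy = drop)", call. = FALSE)
  }
  log <- sprintf("QC: dropped %d of %d sequence(s) with non-ACGT characters",
                 length(flagged), nrow(targets))
  list(targets = kept, log = log)
}

#' Write a QC report table
#'
#' Tab-separated `id, position, char` (positions 1-based in the file).
#' @param reports Reports from [qc_scan()].
#' @param path Output path.
#' @export
write_qc_report <- function(reports, path) {
  header <- "id\tposition\tchar"
  body <- unlist(lapply(names(reports), function(id) {
    r <- reports[[id]]
    if (nrow(r) == 0L) return(character(0))
    sprintf("%s\t%d\t%s", id, r$position + 1L, r$char)
  }))
  writeLines(c(header, body), path)
}
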