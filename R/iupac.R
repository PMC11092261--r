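# IUPAC nucleotide alphabet: code -> set of unambiguous bases.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Membership lookup used by the match engine: row = IUPAC code, column =
# raw character code of a target character. TRUE iff the target character is
# literally one of A/C/G/T in the code's set (a degenerate character in the
# target never matches by set intersection; see the methods vignette).
.iupac_lookup <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = 256,
              dimnames = list(names(IUPAC_CODES), NULL))
  for (code in names(IUPAC_CODES)) {
    m[code, utf8ToInt(paste(IUPAC_CODES[[code]], collapse = ""))] <- TRUE
  }
  m
})

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code Single character, one of the 15 IUPAC nucleotide codes
#'   (`ACGTRYSWKMBDHVN`), case-insensitive.
#' @return Character vector of the unambiguous bases the code stands for,
#'   e.g. `"R"` gives `c("A", "G")` and `"N"` gives all four bases.
#' @examples
#' iupac_class("R")
#' iupac_class("N")
#' @export
iupac_class <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L) {
    stop("'code' must be a single character", call. = FALSE)
  }
  code <- toupper(code)
  if (!code %in% names(IUPAC_CODES)) {
    stop("unknown IUPAC nucleotide code: '", code, "'", call. = FALSE)
  }
  IUPAC_CODES[[code]]
}

# Positions (1-based) of characters that are not valid IUPAC codes;
# integer(0) when the sequence is clean.
invalid_iupac_positions <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  which(!chars %in% names(IUPAC_CODES))
}

is_iupac <- function(seq) {
  nzchar(seq) && length(invalid_iupac_positions(seq)) == 0L
}

#' Reverse-complement an IUPAC nucleotide sequence
#'
#' Degenerate codes are complemented set-wise (`R` <-> `Y`, `K` <-> `M`,
#' `B` <-> `V`, `D` <-> `H`; `S`, `W` and `N` are self-complementary).
#'
#' @param seq Character vector of IUPAC nucleotide strings.
#' @return Character vector of the same length with each sequence reversed
#'   and complemented.
#' @examples
#' reverse_complement("AAR") # "YTT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("'seq' must be character", call. = FALSE)
  vapply(seq, function(s) {
    s <- toupper(s)
    bad <- invalid_iupac_positions(s)
    if (length(bad)) {
      stop("invalid IUPAC character '", substring(s, bad[1], bad[1]),
           "' at position ", bad[1], call. = FALSE)
    }
    comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
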