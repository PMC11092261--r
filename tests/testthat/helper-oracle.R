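# Independent brute-force oracle for the match engine: a naive double-loop
# sliding-window Hamming scanner with its own IUPAC table. Deliberately
# shares no code with find_primer_hits().

oracle_classes <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_hits <- function(primer, target, max_mm) {
  p <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  t <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
  m <- length(p)
  n <- length(t)
  starts <- integer(0)
  mms <- integer(0)
  if (m <= n) {
    for (i in 0:(n - m)) {
      mm <- 0L
      for (j in seq_len(m)) {
        if (!(t[i + j] %in% oracle_classes[[p[j]]])) {
          mm <- mm + 1L
          if (mm > max_mm) break
        }
      }
      if (mm <= max_mm) {
        starts <- c(starts, i)
        mms <- c(mms, mm)
      }
    }
  }
  data.frame(start = starts, mismatches = mms)
}

random_iupac_primer <- function(len, degen_frac) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  n_deg <- rbinom(1L, len, degen_frac)
  if (n_deg > 0L) {
    pos <- sample.int(len, n_deg)
    chars[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"),
                         n_deg, replace = TRUE)
  }
  paste(chars, collapse = "")
}

random_target <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
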