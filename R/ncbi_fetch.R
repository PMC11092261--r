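# Batched retrieval of nucleotide sequences (and lineages) by accession id.
# All network access is isolated behind an injected transport object, so the
# module is fully unit-testable offline; the real transport talks to the
# NCBI E-utilities nucleotide endpoints.

#' Split accession ids into download batches
#'
#' Duplicated ids are removed (first occurrence wins) before batching; the
#' batches partition the ids in order, all of size `batch_size` except
#' possibly the last.
#'
#' @param ids Character vector of accession identifiers.
#' @param batch_size Positive batch size (default 100).
#' @return List of character vectors.
#' @export
plan_batches <- function(ids, batch_size = 100L) {
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (length(ids) == 0L) stop("no accession ids given", call. = FALSE)
  if (anyDuplicated(ids)) {
    message(sum(duplicated(ids)), " duplicated id(s) removed before batching")
    ids <- ids[!duplicated(ids)]
  }
  unname(split(ids, ceiling(seq_along(ids) / batch_size)))
}

#' An in-memory transport for offline use and tests
#'
#' @param sequences Named character vector: accession -> sequence. Requests
#'   for ids absent from it are simply missing from the response.
#' @param lineages Optional named character vector: accession ->
#'   semicolon-joined lineage.
#' @param fail_times Number of initial calls that raise an error before the
#'   transport starts answering (exercises the retry policy).
#' @return Transport list with `get_sequences(ids)` and `get_taxonomy(ids)`.
#' @export
stub_transport <- function(sequences, lineages = NULL, fail_times = 0L) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  maybe_fail <- function() {
    calls$n <- calls$n + 1L
    if (calls$n <= fail_times) stop("stub transport: simulated failure")
  }
  list(
    get_sequences = function(ids) {
      maybe_fail()
      sequences[ids[ids %in% names(sequences)]]
    },
    get_taxonomy = function(ids) {
      maybe_fail()
      if (is.null(lineages)) stop("stub transport has no taxonomy")
      lineages[ids[ids %in% names(lineages)]]
    }
  )
}

#' Transport backed by the NCBI E-utilities nucleotide endpoints
#'
#' Sequences come from `efetch` (`rettype=fasta`); lineages are scraped from
#' the `ORGANISM`/lineage block of `rettype=gb` records. Requires network
#' access and is never exercised by the test suite; supply a contact e-mail
#' per the NCBI usage policy.
#'
#' @param email Contact e-mail passed to the service (required).
#' @param api_key Optional NCBI API key.
#' @param db Entrez database (default `"nuccore"`).
#' @return Transport list compatible with [fetch_job()].
#' @export
ncbi_transport <- function(email, api_key = NULL, db = "nuccore") {
  if (missing(email) || !nzchar(email)) {
    stop("an e-mail address is required by the NCBI usage policy",
         call. = FALSE)
  }
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
  query <- function(ids, rettype) {
    url <- paste0(base, "?db=", db, "&id=", paste(ids, collapse = ","),
                  "&rettype=", rettype, "&retmode=text",
                  "&email=", utils::URLencode(email, reserved = TRUE),
                  if (!is.null(api_key)) paste0("&api_key=", api_key) else "")
    readLines(url, warn = FALSE)
  }
  list(
    get_sequences = function(ids) {
      lines <- query(ids, "fasta")
      tmp <- tempfile(fileext = ".fasta")
      on.exit(unlink(tmp))
      writeLines(lines, tmp)
      fa <- read_fasta(tmp)
      # efetch returns versioned accessions; report under the requested id
      hit <- match(vapply(strsplit(fa$id, ".", fixed = TRUE), `[`,
                          character(1), 1L),
                   vapply(strsplit(ids, ".", fixed = TRUE), `[`,
                          character(1), 1L))
      out <- fa$sequence[!is.na(hit)]
      names(out) <- ids[hit[!is.na(hit)]]
      out
    },
    get_taxonomy = function(ids) {
      out <- character(0)
      lines <- query(ids, "gb")
      acc <- NA_character_
      collecting <- FALSE
      lineage <- character(0)
      flush <- function() {
        if (!is.na(acc) && length(lineage)) {
          out[acc] <<- paste(trimws(strsplit(paste(lineage, collapse = " "),
                                             ";")[[1]]), collapse = ";")
        }
      }
      for (ln in lines) {
        if (grepl("^ACCESSION", ln)) {
          flush()
          acc <- strsplit(trimws(sub("^ACCESSION", "", ln)), " +")[[1]][1]
          lineage <- character(0)
          collecting <- FALSE
        } else if (grepl("^  ORGANISM", ln)) {
          collecting <- TRUE
        } else if (collecting) {
          if (grepl("^ {4,}\\S", ln)) lineage <- c(lineage, trimws(ln))
          else collecting <- FALSE
        }
      }
      flush()
      out <- sub("\\.$", "", out)
      out[ids[ids %in% names(out)]]
    }
  )
}

#' Download sequences (and lineages) batch by batch
#'
#' Ids are deduplicated, batched, and fetched through the transport with a
#' retry policy; successfully retrieved records are written in the original
#' input order regardless of batch boundaries, and ids that still fail after
#' the retries are reported, never silently dropped.
#'
#' @param ids Accession identifiers.
#' @param out_fasta Output FASTA path.
#' @param transport A transport: [stub_transport()] or [ncbi_transport()].
#' @param batch_size Ids per request (default 100).
#' @param retrieve_taxonomy Also fetch lineages and write a `.tax` file next
#'   to the FASTA (same basename, semicolon lineage format).
#' @param max_attempts Attempts per batch (default 3).
#' @param backoff Seconds to wait between attempts and between batches
#'   (default 0.4; set to 0 in tests).
#' @return List `n_written`, `failed_ids`, `tax_path` (`NULL` unless
#'   taxonomy was retrieved). Error if every batch fails.
#' @export
fetch_job <- function(ids, out_fasta, transport, batch_size = 100L,
                      retrieve_taxonomy = FALSE, max_attempts = 3L,
                      backoff = 0.4) {
  batches <- plan_batches(ids, batch_size)
  uids <- unlist(batches)
  seqs <- character(0)
  taxs <- character(0)
  failed <- character(0)
  n_batch_fail <- 0L
  with_retry <- function(f, batch) {
    for (attempt in seq_len(max_attempts)) {
      res <- tryCatch(f(batch), error = function(e) e)
      if (!inherits(res, "error")) return(res)
      if (attempt < max_attempts && backoff > 0) Sys.sleep(backoff)
    }
    NULL
  }
  for (b in seq_along(batches)) {
    batch <- batches[[b]]
    got <- with_retry(transport$get_sequences, batch)
    if (is.null(got)) {
      n_batch_fail <- n_batch_fail + 1L
      failed <- c(failed, batch)
      next
    }
    seqs <- c(seqs, got)
    failed <- c(failed, setdiff(batch, names(got)))
    if (retrieve_taxonomy) {
      tax <- with_retry(transport$get_taxonomy, names(got))
      taxs <- c(taxs, tax)
    }
    if (b < length(batches) && backoff > 0) Sys.sleep(backoff)
  }
  if (n_batch_fail == length(batches)) {
    stop("all ", length(batches), " batch(es) failed", call. = FALSE)
  }
  ok <- uids[uids %in% names(seqs)]  # input order, not arrival order
  writeLines(as.vector(rbind(paste0(">", ok), unname(seqs[ok]))), out_fasta)
  tax_path <- NULL
  if (retrieve_taxonomy) {
    tax_path <- default_taxonomy_path(out_fasta)
    with_tax <- ok[ok %in% names(taxs)]
    writeLines(paste0(with_tax, "\t", unname(taxs[with_tax]), ";"), tax_path)
  }
  list(n_written = length(ok), failed_ids = failed, tax_path = tax_path)
}
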