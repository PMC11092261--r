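# Analysis grouping and coverage arithmetic. A group is a set of sequence
# ids: one per sequence (default), one per taxon at a chosen level (sequences
# sharing the lineage prefix up to that level), or one per clade (every
# distinct non-empty lineage prefix of any depth; clades nest). Group keys
# are full semicolon-joined prefixes so homonymous taxa at different
# positions never merge.

#' Form analysis groups
#'
#' @param targets data.frame from [read_fasta()] (after QC).
#' @param lineages Named list id -> taxon vector from [read_taxonomy()];
#'   required for `mode = "level"` and `mode = "clades"`. Sequences without a
#'   lineage are excluded from those modes (the count is recorded in the
#'   `"n_excluded"` attribute, and ids in `"excluded_ids"`).
#' @param mode `"none"` (one group per sequence), `"level"` (one group per
#'   taxon at `level`), or `"clades"` (one group per lineage prefix).
#' @param level Level name (must be one of the taxonomy's level names) when
#'   `mode = "level"`.
#' @return Named list mapping group key to a character vector of member ids.
#'   In `"none"` and `"level"` modes the groups partition the analysed
#'   sequences; in `"clades"` mode a clade contains its descendants' members.
#' @examples
#' tg <- data.frame(id = c("s1", "s2"), sequence = c("ACGT", "ACGT"))
#' make_groups(tg, mode = "none")
#' @export
make_groups <- function(targets, lineages = NULL,
                        mode = c("none", "level", "clades"), level = NULL) {
  mode <- match.arg(mode)
  ids <- targets$id
  if (mode == "none") {
    groups <- as.list(ids)
    names(groups) <- ids
    attr(groups, "n_excluded") <- 0L
    attr(groups, "excluded_ids") <- character(0)
    return(groups)
  }
  if (is.null(lineages)) {
    stop("mode '", mode, "' requires taxonomy lineages", call. = FALSE)
  }
  level_names <- attr(lineages, "level_names")
  with_tax <- ids[ids %in% names(lineages)]
  excluded <- setdiff(ids, with_tax)
  if (length(with_tax) == 0L) {
    stop("no analysed sequence has a taxonomy lineage", call. = FALSE)
  }
  keys_per_id <- if (mode == "level") {
    if (is.null(level) || !level %in% level_names) {
      stop("unknown taxonomic level '", level, "'; valid levels: ",
           paste(level_names, collapse = ", "), call. = FALSE)
    }
    k <- match(level, level_names)
    lapply(with_tax, function(id)
      paste(lineages[[id]][seq_len(k)], collapse = ";"))
  } else {
    lapply(with_tax, function(id) {
      lin <- lineages[[id]]
      vapply(seq_along(lin), function(d)
        paste(lin[seq_len(d)], collapse = ";"), character(1))
    })
  }
  pairs <- data.frame(
    key = unlist(keys_per_id),
    id = rep(with_tax, lengths(keys_per_id)),
    stringsAsFactors = FALSE
  )
  groups <- split(pairs$id, pairs$key)  # split() sorts keys: deterministic
  groups <- lapply(groups, unique)
  attr(groups, "n_excluded") <- length(excluded)
  attr(groups, "excluded_ids") <- excluded
  groups
}

#' Coverage of a set of groups by a set of matched sequences
#'
#' A group is covered when at least one of its member sequences is covered.
#'
#' @param groups Named list from [make_groups()].
#' @param covered_ids Character vector of covered sequence ids.
#' @return List with `n_groups`, `n_covered` and `coverage_pct`
#'   (`100 * n_covered / n_groups`, unrounded).
#' @export
coverage_percent <- function(groups, covered_ids) {
  n_groups <- length(groups)
  if (n_groups == 0L) stop("no groups to assess", call. = FALSE)
  n_covered <- sum(vapply(groups, function(m) any(m %in% covered_ids),
                          logical(1)))
  list(n_groups = n_groups, n_covered = n_covered,
       coverage_pct = 100 * n_covered / n_groups)
}

#' Per-group coverage: fraction of member sequences covered
#'
#' @inheritParams coverage_percent
#' @return Named numeric vector: for each group key,
#'   `100 * |members covered| / |members|`.
#' @export
per_group_coverage <- function(groups, covered_ids) {
  vapply(groups, function(m) 100 * sum(m %in% covered_ids) / length(m),
         numeric(1))
}

#' Mean start/end position (and amplicon length) over representative hits
#'
#' Positions are converted to the reporting convention: 1-based start,
#' 1-based inclusive end. With one representative hit per covered sequence,
#' multi-hit sequences do not dominate the averages.
#'
#' @param rep_hits data.frame of representative hits (0-based half-open
#'   `start`/`end`, optional `length` column for amplicons); zero rows allowed.
#' @return List `mean_start`, `mean_end`, `mean_length` (all `NA` when there
#'   are no hits; `mean_length` `NA` for single primers).
#' @export
position_summary <- function(rep_hits) {
  if (is.null(rep_hits) || nrow(rep_hits) == 0L) {
    return(list(mean_start = NA_real_, mean_end = NA_real_,
                mean_length = NA_real_))
  }
  list(
    mean_start = mean(rep_hits$start + 1),
    mean_end = mean(rep_hits$end),
    mean_length = if ("length" %in% names(rep_hits)) mean(rep_hits$length)
                  else NA_real_
  )
}
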