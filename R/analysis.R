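# Orchestration: single-primer runs (analyze_ip), primer-pair runs
# (analyze_pp) and the case-study procedure (species-level domain
# classification, threshold-based pair construction, pair re-evaluation).
# All stages are deterministic; rerunning with identical inputs produces
# byte-identical output files (no timestamps are written anywhere).

#' Build a run configuration
#'
#' @param max_mismatches Substitution budget per primer (default 0: no
#'   mismatches allowed).
#' @param mode Grouping mode: `"none"`, `"level"` or `"clades"`.
#' @param level Level name for `mode = "level"`.
#' @param min_len,max_len Optional amplicon length bounds (pairs only).
#' @param rc_reverse Reverse-complement reverse primers before searching
#'   (default `FALSE`: primers are taken as written, already oriented for
#'   amplification).
#' @param qc_policy `"keep"` or `"drop"` for sequences with non-ACGT
#'   characters.
#' @param out_dir Output directory; `NULL` suppresses all file output.
#' @param per_group Also compute/write per-group coverage tables.
#' @param threshold_pct Species-level coverage threshold for pair
#'   construction in the case study (default 75).
#' @param domain_min_cov Coverage strictly above this counts as "covers the
#'   domain" when classifying primers (default 0).
#' @return A list of settings with class `"pe_config"`.
#' @export
run_config <- function(max_mismatches = 0L, mode = c("none", "level", "clades"),
                       level = NULL, min_len = NULL, max_len = NULL,
                       rc_reverse = FALSE, qc_policy = c("keep", "drop"),
                       out_dir = NULL, per_group = FALSE,
                       threshold_pct = 75, domain_min_cov = 0) {
  mode <- match.arg(mode)
  qc_policy <- match.arg(qc_policy)
  if (max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  if (!is.null(min_len) && !is.null(max_len) && min_len > max_len) {
    stop("min_len must be <= max_len", call. = FALSE)
  }
  if (mode == "level" && is.null(level)) {
    stop("mode 'level' requires a level name", call. = FALSE)
  }
  structure(list(max_mismatches = as.integer(max_mismatches), mode = mode,
                 level = level, min_len = min_len, max_len = max_len,
                 rc_reverse = isTRUE(rc_reverse), qc_policy = qc_policy,
                 out_dir = out_dir, per_group = isTRUE(per_group),
                 threshold_pct = threshold_pct,
                 domain_min_cov = domain_min_cov),
            class = "pe_config")
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # implied by the file's location; keeps reruns byte-identical
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# Shared front half of both analyses: QC, grouping, bookkeeping.
prepare_run <- function(targets, lineages, config) {
  if (nrow(targets) == 0L) stop("empty sequence database", call. = FALSE)
  reports <- qc_scan(targets)
  pol <- apply_policy(targets, reports, config$qc_policy)
  groups <- make_groups(pol$targets, lineages, config$mode, config$level)
  log <- pol$log
  if (attr(groups, "n_excluded") > 0L) {
    log <- c(log, sprintf(
      "grouping: excluded %d sequence(s) without taxonomy",
      attr(groups, "n_excluded")))
  }
  analysed_ids <- unique(unlist(groups, use.names = FALSE))
  seqs <- pol$targets$sequence[match(analysed_ids, pol$targets$id)]
  names(seqs) <- analysed_ids
  list(targets = pol$targets, groups = groups, seqs = seqs,
       qc_reports = reports, log = log)
}

coverage_row <- function(name, cov, ps, pair = FALSE) {
  data.frame(primer_name = name, n_groups = cov$n_groups,
             n_covered = cov$n_covered, coverage_pct = cov$coverage_pct,
             mean_start = ps$mean_start, mean_end = ps$mean_end,
             mean_amplicon_length = if (pair) ps$mean_length else NA_real_,
             stringsAsFactors = FALSE)
}

#' Analyse single primers against a sequence database
#'
#' For every primer: QC, grouping, mismatch-tolerant search over every
#' analysed sequence (unknown-role primers are searched both as written and
#' reverse-complemented; a hit in either orientation counts), then coverage
#' and positional summaries. The representative hit per covered sequence is
#' the leftmost (ties broken by end), so multi-hit sequences contribute once
#' to the mean start/end.
#'
#' @param primers Primer data.frame from [read_oligos()] with roles among
#'   forward/reverse/unknown.
#' @param targets data.frame from [read_fasta()].
#' @param lineages Optional taxonomy from [read_taxonomy()] (required for
#'   taxonomic grouping modes).
#' @param config A [run_config()].
#' @return List with `coverage` (one row per primer), `details` (per primer:
#'   `covered_ids`, `rep_hits`, `hits`), `groups` and `log`. When
#'   `config$out_dir` is set, also writes `coverage_ip.tsv`, one
#'   `ip_<name>_hits.fasta` per primer, and (with `per_group`) per-group
#'   coverage tables.
#' @export
analyze_ip <- function(primers, targets, lineages = NULL, config = run_config()) {
  if (nrow(primers) == 0L) stop("empty primer list", call. = FALSE)
  if (any(primers$role == "pair")) {
    stop("analyze_ip takes single primers; use analyze_pp for pairs",
         call. = FALSE)
  }
  prep <- prepare_run(targets, lineages, config)
  rows <- vector("list", nrow(primers))
  details <- vector("list", nrow(primers))
  for (i in seq_len(nrow(primers))) {
    p <- primers[i, ]
    per_seq <- lapply(names(prep$seqs), function(id) {
      h <- find_primer_hits(p$sequence, prep$seqs[[id]], config$max_mismatches)
      if (p$role == "unknown") {
        h2 <- find_primer_hits(reverse_complement(p$sequence), prep$seqs[[id]],
                               config$max_mismatches)
        h <- rbind(h, h2)
        h <- h[order(h$start, h$end), , drop = FALSE]
      }
      if (nrow(h)) h$target_id <- id
      h
    })
    per_seq <- per_seq[vapply(per_seq, nrow, integer(1)) > 0L]
    hits <- if (length(per_seq)) do.call(rbind, per_seq) else {
      cbind(empty_hits(), data.frame(target_id = character(0)))
    }
    rep_hits <- if (length(per_seq)) {
      do.call(rbind, lapply(per_seq, function(h) h[1L, , drop = FALSE]))
    } else empty_hits()
    covered <- unique(hits$target_id)
    cov <- coverage_percent(prep$groups, covered)
    rows[[i]] <- coverage_row(p$name, cov, position_summary(rep_hits))
    details[[i]] <- list(covered_ids = covered, rep_hits = rep_hits, hits = hits)
  }
  coverage <- do.call(rbind, rows)
  rownames(coverage) <- NULL
  names(details) <- primers$name
  res <- list(coverage = coverage, details = details, groups = prep$groups,
              log = prep$log)
  if (!is.null(config$out_dir)) {
    write_ip_outputs(res, primers, config)
  }
  res
}

write_ip_outputs <- function(res, primers, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_coverage_table(res$coverage,
                       file.path(config$out_dir, "coverage_ip.tsv"))
  for (nm in primers$name) {
    write_amplicon_fasta(res$details[[nm]]$hits,
      file.path(config$out_dir, sprintf("ip_%s_hits.fasta", safe_name(nm))))
    if (config$per_group) {
      pct <- per_group_coverage(res$groups, res$details[[nm]]$covered_ids)
      write_group_coverage(res$groups, pct,
        file.path(config$out_dir, sprintf("group_coverage_%s.tsv", safe_name(nm))))
    }
  }
}

#' Analyse primer pairs against a sequence database
#'
#' As [analyze_ip()], but a sequence counts as covered when
#' [find_amplicons()] yields at least one amplicon within the configured
#' length bounds; summaries (mean start/end/amplicon length) use the
#' representative amplicon per covered sequence (leftmost, then shortest).
#'
#' @param pairs Primer data.frame with role `"pair"` rows (columns
#'   `fwd_sequence`, `rev_sequence`).
#' @inheritParams analyze_ip
#' @return As [analyze_ip()]; coverage rows carry `mean_amplicon_length`,
#'   and per-pair FASTA files (`pp_<name>_amplicons.fasta`) contain the
#'   representative amplicon of each covered sequence.
#' @export
analyze_pp <- function(pairs, targets, lineages = NULL, config = run_config()) {
  if (nrow(pairs) == 0L) stop("empty primer-pair list", call. = FALSE)
  if (any(pairs$role != "pair")) {
    stop("analyze_pp takes pair records only", call. = FALSE)
  }
  prep <- prepare_run(targets, lineages, config)
  rows <- vector("list", nrow(pairs))
  details <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    per_seq <- lapply(names(prep$seqs), function(id) {
      a <- find_amplicons(p$fwd_sequence, p$rev_sequence, prep$seqs[[id]],
                          config$max_mismatches, config$min_len,
                          config$max_len, config$rc_reverse)
      if (nrow(a)) a$target_id <- id
      a
    })
    per_seq <- per_seq[vapply(per_seq, nrow, integer(1)) > 0L]
    rep_hits <- if (length(per_seq)) {
      do.call(rbind, lapply(per_seq, function(a) a[1L, , drop = FALSE]))
    } else empty_amplicons()
    covered <- unique(rep_hits$target_id)
    cov <- coverage_percent(prep$groups, covered)
    rows[[i]] <- coverage_row(p$name, cov, position_summary(rep_hits),
                              pair = TRUE)
    details[[i]] <- list(covered_ids = covered, rep_hits = rep_hits)
  }
  coverage <- do.call(rbind, rows)
  rownames(coverage) <- NULL
  names(details) <- pairs$name
  res <- list(coverage = coverage, details = details, groups = prep$groups,
              log = prep$log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_coverage_table(coverage, file.path(config$out_dir, "coverage_pp.tsv"))
    for (nm in pairs$name) {
      write_amplicon_fasta(details[[nm]]$rep_hits,
        file.path(config$out_dir,
                  sprintf("pp_%s_amplicons.fasta", safe_name(nm))))
      if (config$per_group) {
        pct <- per_group_coverage(res$groups, details[[nm]]$covered_ids)
        write_group_coverage(res$groups, pct,
          file.path(config$out_dir,
                    sprintf("group_coverage_%s.tsv", safe_name(nm))))
      }
    }
  }
  res
}

#' Classify primers by the domain(s) they cover
#'
#' A primer "covers" a domain when its coverage on that domain's database is
#' strictly above `min_cov` (default 0): both -> universal, neither -> none.
#'
#' @param bacterial_rows,archaeal_rows Coverage data.frames (same primer set,
#'   typically species-level).
#' @param min_cov Coverage threshold (exclusive) for counting a domain as
#'   covered.
#' @return data.frame `primer_name`, `call` (bacteria / archaea / universal /
#'   none), `bacterial_cov_pct`, `archaeal_cov_pct`.
#' @export
classify_domains <- function(bacterial_rows, archaeal_rows, min_cov = 0) {
  only <- c(setdiff(bacterial_rows$primer_name, archaeal_rows$primer_name),
            setdiff(archaeal_rows$primer_name, bacterial_rows$primer_name))
  if (length(only)) {
    stop("primer(s) present in only one coverage table: ",
         paste(only, collapse = ", "), call. = FALSE)
  }
  b <- bacterial_rows$coverage_pct
  a <- archaeal_rows$coverage_pct[match(bacterial_rows$primer_name,
                                        archaeal_rows$primer_name)]
  call <- ifelse(b > min_cov & a > min_cov, "universal",
          ifelse(b > min_cov, "bacteria",
          ifelse(a > min_cov, "archaea", "none")))
  data.frame(primer_name = bacterial_rows$primer_name, call = call,
             bacterial_cov_pct = b, archaeal_cov_pct = a,
             stringsAsFactors = FALSE)
}

#' Count domain calls
#'
#' @param calls data.frame from [classify_domains()].
#' @return Named integer vector over bacteria, archaea, universal, none;
#'   sums to the number of primers.
#' @export
domain_counts <- function(calls) {
  vapply(c("bacteria", "archaea", "universal", "none"),
         function(k) sum(calls$call == k), integer(1))
}

#' Build all candidate primer pairs above a coverage threshold
#'
#' Primers whose (unrounded) coverage is at least `threshold_pct` are
#' eligible; forward and unknown primers may serve as forward partner,
#' reverse and unknown primers as reverse partner. The full cross product is
#' emitted, pair names `<fwd>-<rev>`.
#'
#' @param rows Coverage data.frame augmented with `role` and `sequence`
#'   columns for each primer.
#' @param threshold_pct Eligibility threshold (default 75).
#' @return Primer data.frame of role-`"pair"` records (possibly empty, with
#'   a warning when either side has no eligible primer).
#' @export
build_candidate_pairs <- function(rows, threshold_pct = 75) {
  stopifnot(all(c("primer_name", "coverage_pct", "role", "sequence") %in%
                names(rows)))
  elig <- rows[rows$coverage_pct >= threshold_pct, , drop = FALSE]
  fwd <- elig[elig$role %in% c("forward", "unknown"), , drop = FALSE]
  rev <- elig[elig$role %in% c("reverse", "unknown"), , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    warning("no eligible ", if (nrow(fwd) == 0L) "forward" else "reverse",
            " primers at threshold ", threshold_pct, call. = FALSE)
    return(primer_df())
  }
  combos <- expand.grid(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rev)))
  primer_df(
    name = paste0(fwd$primer_name[combos$fi], "-", rev$primer_name[combos$ri]),
    role = "pair",
    sequence = NA_character_,
    fwd_sequence = fwd$sequence[combos$fi],
    rev_sequence = rev$sequence[combos$ri]
  )
}

rank_pair_table <- function(coverage) {
  if (is.null(coverage) || nrow(coverage) == 0L) return(coverage)
  ord <- order(-coverage$coverage_pct, is.na(coverage$mean_amplicon_length),
               coverage$mean_amplicon_length, coverage$primer_name)
  out <- coverage[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full case-study procedure on two databases
#'
#' Single primers are evaluated at the configured taxonomic level on both a
#' bacterial and an archaeal database; primers are classified by the domain
#' they actually cover; per domain, primers reaching `threshold_pct` coverage
#' are combined into all forward x reverse candidate pairs, which are then
#' re-evaluated on that domain's database and ranked (coverage descending,
#' mean amplicon length ascending, then name).
#'
#' @param primers Primer data.frame; pair records are ignored with a log
#'   note (the case study evaluates single primers and builds its own pairs).
#' @param bact_targets,arch_targets Sequence databases from [read_fasta()].
#' @param bact_lineages,arch_lineages Taxonomies from [read_taxonomy()].
#' @param config A [run_config()]; `mode`/`level` select the grouping
#'   (species level in the published case study).
#' @return List with `domain_calls`, `domain_counts`, `pairs` (ranked
#'   coverage tables per domain) and `ip` (the two single-primer runs).
#'   With `out_dir` set, writes per-stage subdirectories, the domain
#'   classification/count tables, ranked pair tables, `run_config.json`
#'   and `run.log`.
#' @export
run_case_study <- function(primers, bact_targets, bact_lineages,
                           arch_targets, arch_lineages, config = run_config()) {
  log <- character(0)
  singles <- primers[primers$role != "pair", , drop = FALSE]
  if (nrow(singles) < nrow(primers)) {
    log <- c(log, sprintf("case-study: ignored %d pair record(s)",
                          nrow(primers) - nrow(singles)))
  }
  if (nrow(singles) == 0L) stop("no single primers to analyse", call. = FALSE)
  sub_cfg <- function(sub) {
    cfg <- config
    cfg$out_dir <- if (is.null(config$out_dir)) NULL
                   else file.path(config$out_dir, sub)
    cfg
  }
  ip_b <- analyze_ip(singles, bact_targets, bact_lineages, sub_cfg("ip_bacteria"))
  ip_a <- analyze_ip(singles, arch_targets, arch_lineages, sub_cfg("ip_archaea"))
  calls <- classify_domains(ip_b$coverage, ip_a$coverage, config$domain_min_cov)
  counts <- domain_counts(calls)
  aug <- function(cov) {
    cov$role <- singles$role[match(cov$primer_name, singles$name)]
    cov$sequence <- singles$sequence[match(cov$primer_name, singles$name)]
    cov
  }
  run_pp <- function(cov_rows, targets, lineages, sub) {
    cand <- withCallingHandlers(
      build_candidate_pairs(aug(cov_rows), config$threshold_pct),
      warning = function(w) {
        log <<- c(log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (nrow(cand) == 0L) return(NULL)
    analyze_pp(cand, targets, lineages, sub_cfg(sub))
  }
  pp_b <- run_pp(ip_b$coverage, bact_targets, bact_lineages, "pp_bacteria")
  pp_a <- run_pp(ip_a$coverage, arch_targets, arch_lineages, "pp_archaea")
  ranked <- list(bacteria = rank_pair_table(if (is.null(pp_b)) NULL else pp_b$coverage),
                 archaea = rank_pair_table(if (is.null(pp_a)) NULL else pp_a$coverage))
  log <- c(log, ip_b$log, ip_a$log,
           sprintf("domain counts: bacteria=%d archaea=%d universal=%d none=%d",
                   counts["bacteria"], counts["archaea"], counts["universal"],
                   counts["none"]))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(calls, file.path(config$out_dir, "domain_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c("call\tn", sprintf("%s\t%d", names(counts), counts)),
               file.path(config$out_dir, "domain_counts.tsv"))
    for (dom in names(ranked)) {
      if (!is.null(ranked[[dom]])) {
        write_coverage_table(ranked[[dom]],
          file.path(config$out_dir, sprintf("ranked_pairs_%s.tsv", dom)))
      }
    }
    write_run_config(config, file.path(config$out_dir, "run_config.json"))
    writeLines(log, file.path(config$out_dir, "run.log"))
  }
  list(domain_calls = calls, domain_counts = counts, pairs = ranked,
       ip = list(bacteria = ip_b, archaea = ip_a), log = log)
}
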