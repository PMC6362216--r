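#' Chimera-scan parameters
#'
#' Quantifies the split-and-compare screening logic: a sequence is chimeric
#' when its two sides best-match references from different clades, each side
#' matching its own parent about as well as the whole sequence matches
#' anything (`delta_support`), while matching the other side's parent
#' substantially worse (`delta_conflict`). The defaults (1% and 3%) separate
#' a within-clade identity regime (above roughly 98.6%) from a between-clade
#' regime (below roughly 98.5%).
#'
#' @param scan_step breakpoint scan step in nt
#' @param end_margin no breakpoints closer than this to either end (nt)
#' @param delta_support max identity shortfall of a half versus the full
#'   query's identity to that half's parent, percent
#' @param delta_conflict min identity drop of a half against the *other*
#'   half's parent, percent
#' @return object of class `chimera_params`
#' @export
chimera_params <- function(scan_step = 10L, end_margin = 100L,
                           delta_support = 1.0, delta_conflict = 3.0) {
  if (end_margin < scan_step) stop("end_margin must be >= scan_step", call. = FALSE)
  if (delta_support <= 0 || delta_conflict <= 0) {
    stop("deltas must be > 0", call. = FALSE)
  }
  structure(list(scan_step = as.integer(scan_step),
                 end_margin = as.integer(end_margin),
                 delta_support = delta_support,
                 delta_conflict = delta_conflict),
            class = "chimera_params")
}

#' Best-matching reference for a query
#'
#' Exhaustive pairwise identity of the query against a curated local
#' reference set (the screening role a BLAST search plays against a public
#' database, made self-contained and deterministic). Ties are broken by the
#' lexicographically smallest reference id.
#'
#' @param query query sequence
#' @param refs named `DNAStringSet` (or named character vector) of references
#' @return list with `ref_id` and `identity` (percent)
#' @export
best_hit <- function(query, refs) {
  rs <- as_seq_chars(refs)
  if (length(rs) == 0L) stop("reference set is empty", call. = FALSE)
  recs <- align_batch(rs, query)
  ids <- vapply(recs, function(aln) {
    prof <- alignment_profile(aln)
    if (prof$n_col == 0L) 0 else 100 * sum(prof$match) / prof$n_col
  }, numeric(1))
  ord <- order(-ids, names(rs))
  list(ref_id = names(rs)[ord[1L]], identity = round(ids[[ord[1L]]], 1))
}

# per-reference alignment summaries reused across all breakpoints:
# cumulative matches and the query-position -> column map
.query_ref_profiles <- function(query, refs) {
  # one vectorized call: references as patterns, the query as subject;
  # the query-position map is therefore the subject fill of each profile
  recs <- align_batch(as.character(refs), query)
  lapply(recs, function(aln) {
    prof <- alignment_profile(aln)
    list(cum_match = cumsum(prof$match), q_fill = prof$s_fill,
         n_col = prof$n_col,
         full_identity = if (prof$n_col == 0L) 0 else
           100 * sum(prof$match) / prof$n_col)
  })
}

# identity of query[1..b] and query[(b+1)..L] to one reference, from the
# full-alignment column prefix sums
.half_identities <- function(p, b) {
  idx <- findInterval(b, p$q_fill)
  pre <- if (idx >= 1L) 100 * p$cum_match[idx] / idx else 0
  n_suf <- p$n_col - idx
  suf <- if (n_suf >= 1L) {
    100 * (p$cum_match[p$n_col] - if (idx >= 1L) p$cum_match[idx] else 0) / n_suf
  } else 0
  c(prefix = pre, suffix = suf)
}

#' Split-and-compare chimera classification
#'
#' For every candidate breakpoint `b` between `end_margin` and
#' `L - end_margin` (stepped by `scan_step`), the identities of the prefix
#' `query[1..b]` and the suffix `query[(b+1)..L]` against every reference
#' are evaluated, and the breakpoint maximizing (best prefix identity +
#' best suffix identity) is examined. The query is called a chimera when
#' (i) each half matches its own parent at least as well as the full query
#' does, minus `delta_support`; (ii) the two parents belong to different
#' clades; and (iii) each half matches the other half's parent worse by at
#' least `delta_conflict`. Otherwise it is clean.
#'
#' The full query is aligned once against every reference and half
#' identities are derived from alignment-column prefix sums, which is exact
#' for substitution-only divergence and a tight approximation otherwise.
#'
#' @param query query sequence (character or `DNAString`)
#' @param refs named references
#' @param clades named character vector mapping reference id -> clade label
#'   (e.g. from [clade_table()])
#' @param params a [chimera_params()]
#' @param query_id id used in the verdict
#' @return object of class `chimera_verdict`: list with `query_id`,
#'   `verdict` ("clean" or "chimera"), `breakpoint`, `parent_a`/`parent_b`
#'   (prefix/suffix parents) with clades, and the four half identities
#' @export
classify_chimera <- function(query, refs, clades, params = chimera_params(),
                             query_id = "query") {
  q <- as_seq_string(query)
  L <- nchar(q)
  if (L <= 2L * params$end_margin) {
    stop("query '", query_id, "' too short for chimera scan (", L,
         " nt <= 2 x end_margin)", call. = FALSE)
  }
  ref_ids <- names(refs)
  if (is.null(ref_ids)) stop("references must be named", call. = FALSE)
  miss <- setdiff(ref_ids, names(clades))
  if (length(miss) > 0L) {
    stop("no clade label for reference(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  profs <- .query_ref_profiles(q, refs)
  names(profs) <- ref_ids
  bps <- seq.int(params$end_margin, L - params$end_margin,
                 by = params$scan_step)
  best <- NULL
  for (b in bps) {
    hv <- vapply(profs, .half_identities, numeric(2), b = b)
    pre_ord <- order(-hv["prefix", ], ref_ids)[1L]
    suf_ord <- order(-hv["suffix", ], ref_ids)[1L]
    sc <- hv["prefix", pre_ord] + hv["suffix", suf_ord]
    if (is.null(best) || sc > best$score + 1e-9) {
      best <- list(score = sc, b = b,
                   ref_p = ref_ids[pre_ord], ref_s = ref_ids[suf_ord],
                   id_pp = hv["prefix", pre_ord], id_ss = hv["suffix", suf_ord],
                   id_ps = hv["prefix", suf_ord], id_sp = hv["suffix", pre_ord])
    }
  }
  clade_p <- unname(clades[best$ref_p])
  clade_s <- unname(clades[best$ref_s])
  support_ok <-
    best$id_pp >= profs[[best$ref_p]]$full_identity - params$delta_support &&
    best$id_ss >= profs[[best$ref_s]]$full_identity - params$delta_support
  conflict_ok <-
    best$id_ps <= best$id_pp - params$delta_conflict &&
    best$id_sp <= best$id_ss - params$delta_conflict
  is_chimera <- support_ok && clade_p != clade_s && conflict_ok
  structure(list(
    query_id = query_id,
    verdict = if (is_chimera) "chimera" else "clean",
    breakpoint = if (is_chimera) best$b else NA_integer_,
    parent_a = best$ref_p, clade_a = clade_p,
    parent_b = best$ref_s, clade_b = clade_s,
    identity_prefix_a = round(best$id_pp, 1),
    identity_suffix_b = round(best$id_ss, 1),
    identity_prefix_b = round(best$id_ps, 1),
    identity_suffix_a = round(best$id_sp, 1)
  ), class = "chimera_verdict")
}

#' @export
print.chimera_verdict <- function(x, ...) {
  if (x$verdict == "chimera") {
    cat(sprintf("'%s': CHIMERA at ~%d nt (%s [clade %s] | %s [clade %s])\n",
                x$query_id, x$breakpoint, x$parent_a, x$clade_a,
                x$parent_b, x$clade_b))
  } else {
    cat(sprintf("'%s': clean (best hit %s, clade %s)\n",
                x$query_id, x$parent_a, x$clade_a))
  }
  invisible(x)
}

#' Screen a set of queries for chimeras
#'
#' Applies [classify_chimera()] to each query; per-query errors (for example
#' too-short queries) are reported in the table rather than silently
#' skipped.
#'
#' @param queries named query sequences
#' @param refs named references
#' @param clades named vector reference id -> clade label
#' @param params a [chimera_params()]
#' @return object of class `chimera_screen`: list with `report` (one row per
#'   query) and `verdicts` (list of `chimera_verdict`s); the print method
#'   shows chimera/clean counts
#' @export
screen_chimeras <- function(queries, refs, clades, params = chimera_params()) {
  qs <- as_seq_chars(queries)
  if (length(qs) == 0L) {
    return(structure(list(report = data.frame(
      query_id = character(0), verdict = character(0),
      breakpoint = integer(0), parent_a = character(0),
      clade_a = character(0), parent_b = character(0),
      clade_b = character(0), note = character(0), stringsAsFactors = FALSE),
      verdicts = list()), class = "chimera_screen"))
  }
  verdicts <- lapply(names(qs), function(qid) {
    tryCatch(classify_chimera(qs[[qid]], refs, clades, params, query_id = qid),
             error = function(e) {
               structure(list(query_id = qid, verdict = "error",
                              breakpoint = NA_integer_,
                              parent_a = NA_character_, clade_a = NA_character_,
                              parent_b = NA_character_, clade_b = NA_character_,
                              note = conditionMessage(e)),
                         class = "chimera_verdict")
             })
  })
  report <- do.call(rbind, lapply(verdicts, function(v) {
    data.frame(query_id = v$query_id, verdict = v$verdict,
               breakpoint = v$breakpoint,
               parent_a = v$parent_a, clade_a = v$clade_a,
               parent_b = v$parent_b, clade_b = v$clade_b,
               note = if (!is.null(v$note)) v$note else "",
               stringsAsFactors = FALSE)
  }))
  structure(list(report = report, verdicts = verdicts),
            class = "chimera_screen")
}

#' @export
print.chimera_screen <- function(x, ...) {
  tab <- table(x$report$verdict)
  cat("chimera_screen:", nrow(x$report), "queries;",
      sum(x$report$verdict == "chimera"), "chimera,",
      sum(x$report$verdict == "clean"), "clean",
      if ("error" %in% names(tab)) paste0(", ", tab[["error"]], " error(s)") else "",
      "\n")
  invisible(x)
}

#' Dump chimera verdicts as JSON
#' @param screen a `chimera_screen`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_chimera_json <- function(screen, path) {
  stopifnot(inherits(screen, "chimera_screen"))
  jsonlite::write_json(lapply(screen$verdicts, unclass), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
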