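#' Expected GC fraction of an IUPAC oligonucleotide
#'
#' Each position contributes the expected G+C content of its expansion set:
#' G, C, S count 1; A, T, W count 0; R, Y, K, M, N count 0.5; B, V count
#' 2/3; D, H count 1/3.
#'
#' @param seq IUPAC nucleotide string
#' @return GC fraction in `[0, 1]`
#' @export
#' @examples
#' gc_fraction("GGCC")                 # 1
#' gc_fraction("YCTGAAGCAAGCTCCAGC")   # 10.5 / 18
gc_fraction <- function(seq) {
  s <- normalize_seq(seq, id = "probe")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  sum(IUPAC_GC_WEIGHT[chars]) / length(chars)
}

#' Melting temperature of a hybridization probe
#'
#' The classical GC-content formula
#' `Tm = 69.3 + 0.41 * %GC - 650 / L` with `%GC = 100 * gc_fraction(seq)`
#' and `L` the probe length, degenerate bases contributing their expected
#' fractional GC. Reported rounded half-away-from-zero to 0.1 degC. The
#' formula regime requires at least 14 nt.
#'
#' @param seq probe sequence (5'->3', IUPAC)
#' @return melting temperature in degC, one decimal
#' @export
#' @examples
#' melting_temperature("GCCGGGGCTTTTTCTGTTGGT")  # 61.8
#' melting_temperature("CCGTTTGCCACTAACGAC")     # 56.0
melting_temperature <- function(seq) {
  s <- normalize_seq(seq, id = "probe")
  L <- nchar(s)
  if (L < 14L) {
    stop("melting temperature formula requires probes of >= 14 nt", call. = FALSE)
  }
  tm <- 69.3 + 0.41 * (100 * gc_fraction(s)) - 650 / L
  sign(tm) * floor(abs(tm) * 10 + 0.5) / 10
}

#' Construct a probe object
#'
#' Probes are stored antisense (5'->3' as synthesized, complementary to the
#' rRNA/gene sense strand) and matched against gene-sense sequences via
#' their reverse complement. By convention the name encodes the target
#' group and the 5' position of the target site on the reference numbering.
#'
#' @param name probe name, e.g. `"Megenus_487"`
#' @param seq probe sequence, 5'->3' IUPAC, length >= 15
#' @param target_group label of the intended target (clade set or genus)
#' @return object of class `probe` with fields name, seq, target_group,
#'   length, gc_fraction, tm
#' @export
probe <- function(name, seq, target_group = NA_character_) {
  s <- normalize_seq(seq, id = name)
  if (nchar(s) < 15L) stop("probe '", name, "' shorter than 15 nt", call. = FALSE)
  structure(list(name = name, seq = s, target_group = target_group,
                 length = nchar(s), gc_fraction = gc_fraction(s),
                 tm = melting_temperature(s)),
            class = "probe")
}

#' @export
print.probe <- function(x, ...) {
  cat(sprintf("probe %s: 5'-%s-3' (L=%d, GC=%.1f%%, Tm=%.1f degC)%s\n",
              x$name, x$seq, x$length, 100 * x$gc_fraction, x$tm,
              if (!is.na(x$target_group)) paste0(" -> ", x$target_group) else ""))
  invisible(x)
}

#' Read a probe table
#'
#' Tab-separated file with columns `name`, `sequence`, `target_group`.
#'
#' @param path path to TSV file
#' @return list of `probe` objects
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "target_group")
  if (!all(need %in% names(df))) {
    stop("probe table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    probe(df$name[i], df$sequence[i], df$target_group[i])
  })
}

#' Ungapped probe matching with IUPAC awareness
#'
#' Slides the reverse complement of the probe along a gene-sense sequence;
#' at each offset the number of positions whose IUPAC expansion sets do not
#' intersect is counted, and offsets with at most `max_mismatch`
#' mismatches are reported.
#'
#' @param probe a `probe` object or probe sequence (5'->3', antisense)
#' @param gene gene-sense sequence (character or `DNAString`)
#' @param max_mismatch 0 or 1 allowed mismatches
#' @return data.frame with columns position (1-based start of the match on
#'   the gene) and mismatches
#' @export
probe_matches <- function(probe, gene, max_mismatch = 0L) {
  pseq <- if (inherits(probe, "probe")) probe$seq else normalize_seq(probe, "probe")
  g <- normalize_seq(as_seq_string(gene), "gene")
  target <- revcomp(pseq)
  k <- nchar(target)
  L <- nchar(g)
  if (L < k) {
    return(data.frame(position = integer(0), mismatches = integer(0)))
  }
  tc <- strsplit(target, "", fixed = TRUE)[[1L]]
  gcs <- strsplit(g, "", fixed = TRUE)[[1L]]
  noff <- L - k + 1L
  mm <- integer(noff)
  for (j in seq_len(k)) {
    mm <- mm + as.integer(!IUPAC_COMPAT[tc[j], gcs[seq.int(j, j + noff - 1L)]])
  }
  hits <- which(mm <= max_mismatch)
  data.frame(position = hits, mismatches = mm[hits])
}

#' In-silico specificity screen of a probe
#'
#' Counts sequences (not match positions) in disjoint target and non-target
#' sets that carry at least one probe match at 0 and at up to `max_mismatch`
#' mismatches - the TestProbe-style check behind published 0/1-mismatch
#' specificity columns.
#'
#' @param probe a `probe` object or probe sequence
#' @param targets named sequences the probe is designed to hit
#' @param nontargets named sequences the probe must not hit
#' @param max_mismatch highest mismatch level reported (0 or 1)
#' @return object of class `specificity_report`: per mismatch level m, the
#'   counts and ids of target and non-target sequences hit
#' @export
specificity_screen <- function(probe, targets, nontargets, max_mismatch = 1L) {
  ts <- as_seq_chars(targets); ns <- as_seq_chars(nontargets)
  if (length(intersect(names(ts), names(ns))) > 0L) {
    stop("target and non-target sets must be disjoint", call. = FALSE)
  }
  name <- if (inherits(probe, "probe")) probe$name else "probe"
  levels <- 0:max_mismatch
  hit_ids <- function(set, m) {
    names(set)[vapply(set, function(s) {
      nrow(probe_matches(probe, s, max_mismatch = m)) > 0L
    }, logical(1))]
  }
  res <- lapply(levels, function(m) {
    th <- hit_ids(ts, m); nh <- hit_ids(ns, m)
    list(mismatches = m,
         target_hits = length(th), target_ids = th,
         nontarget_hits = length(nh), nontarget_ids = nh)
  })
  names(res) <- paste0("m", levels)
  structure(list(probe_name = name, n_targets = length(ts),
                 n_nontargets = length(ns), levels = res),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("specificity_report for %s (%d targets, %d non-targets):\n",
              x$probe_name, x$n_targets, x$n_nontargets))
  for (lv in x$levels) {
    cat(sprintf("  <=%d mismatches: %d/%d targets, %d non-target hits\n",
                lv$mismatches, lv$target_hits, x$n_targets, lv$nontarget_hits))
  }
  invisible(x)
}

#' Dump a specificity report as JSON
#' @param report a `specificity_report`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_specificity_json <- function(report, path) {
  stopifnot(inherits(report, "specificity_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Design clade-specific probes in a reference window
#'
#' Enumerates every candidate site of the allowed lengths inside the target
#' window (default positions 66-95 of the reference numbering, the
#' hypervariable stretch conventionally used for clade probes), builds the
#' degenerate consensus of the target sequences at that site (degeneracy
#' only where targets vary; sites needing more than `max_degeneracy`
#' degenerate positions are rejected), and emits the reverse-complement
#' (antisense) probe when its melting temperature falls in `tm_range`.
#' Candidates must hit every target and no non-target at 0 mismatches;
#' survivors are ranked by non-target hits at 1 mismatch (ascending), then
#' degeneracy (ascending), then distance of Tm from the middle of
#' `tm_range`.
#'
#' @param targets named sequences of the clade to target
#' @param nontargets named sequences of all other clades
#' @param reference full-length reference defining the coordinate system
#' @param window integer `c(start, end)` of the target region
#' @param lengths allowed probe lengths
#' @param tm_range acceptable melting temperature range, degC
#' @param max_degeneracy maximum degenerate positions in the consensus
#' @param group_name used to build probe names (`<group>_<position>`)
#' @return data.frame of ranked candidates with columns name, seq, length,
#'   gc_pct, tm, degeneracy, hits_target_m0, hits_nontarget_m0,
#'   hits_nontarget_m1; empty with a `diagnostic` attribute when no site
#'   separates targets from non-targets at 0 mismatches
#' @export
design_probes <- function(targets, nontargets, reference,
                          window = c(66L, 95L), lengths = 18:21,
                          tm_range = c(52, 64), max_degeneracy = 2L,
                          group_name = "probe") {
  ts <- as_seq_chars(targets); ns <- as_seq_chars(nontargets)
  if (length(ts) == 0L) stop("no target sequences", call. = FALSE)
  ref <- as_seq_string(reference)
  if (window[2L] > nchar(ref)) stop("window outside reference", call. = FALSE)
  anchors <- lapply(names(ts), function(id) anchor(ts[[id]], ref, id = id))
  names(anchors) <- names(ts)
  cand <- list()
  rejected <- c(short_slice = 0L, degenerate = 0L, tm = 0L, not_specific = 0L)
  for (len in lengths) {
    for (s in seq.int(window[1L], window[2L] - len + 1L)) {
      slices <- vapply(anchors, function(a) {
        slice_region(a, c(s, s + len - 1L))
      }, "")
      if (any(nchar(slices) != len)) {
        rejected["short_slice"] <- rejected["short_slice"] + 1L
        next
      }
      mat <- do.call(rbind, strsplit(slices, "", fixed = TRUE))
      cons <- apply(mat, 2L, function(col) iupac_code(unique(col)))
      degeneracy <- sum(!(cons %in% c("A", "C", "G", "T")))
      if (degeneracy > max_degeneracy) {
        rejected["degenerate"] <- rejected["degenerate"] + 1L
        next
      }
      pseq <- revcomp(paste(cons, collapse = ""))
      tm <- melting_temperature(pseq)
      if (tm < tm_range[1L] || tm > tm_range[2L]) {
        rejected["tm"] <- rejected["tm"] + 1L
        next
      }
      ht0 <- sum(vapply(ts, function(x) {
        nrow(probe_matches(pseq, x, 0L)) > 0L
      }, logical(1)))
      hn0 <- sum(vapply(ns, function(x) {
        nrow(probe_matches(pseq, x, 0L)) > 0L
      }, logical(1)))
      if (ht0 < length(ts) || hn0 > 0L) {
        rejected["not_specific"] <- rejected["not_specific"] + 1L
        next
      }
      hn1 <- sum(vapply(ns, function(x) {
        nrow(probe_matches(pseq, x, 1L)) > 0L
      }, logical(1)))
      cand[[length(cand) + 1L]] <- data.frame(
        name = sprintf("%s_%d", group_name, s), seq = pseq, length = len,
        gc_pct = round(100 * gc_fraction(pseq), 2), tm = tm,
        degeneracy = degeneracy, hits_target_m0 = ht0,
        hits_nontarget_m0 = hn0, hits_nontarget_m1 = hn1,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) {
    out <- data.frame(name = character(0), seq = character(0),
                      length = integer(0), gc_pct = numeric(0),
                      tm = numeric(0), degeneracy = integer(0),
                      hits_target_m0 = integer(0),
                      hits_nontarget_m0 = integer(0),
                      hits_nontarget_m1 = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "diagnostic") <- paste0(
      "no candidate separates targets from non-targets at 0 mismatches ",
      "in window ", window[1L], "-", window[2L], " (rejected: ",
      paste(names(rejected), rejected, sep = "=", collapse = ", "), ")")
    return(out)
  }
  out <- do.call(rbind, cand)
  mid <- mean(tm_range)
  out <- out[order(out$hits_nontarget_m1, out$degeneracy,
                   abs(out$tm - mid), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
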