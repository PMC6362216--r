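#' Genus screen for short amplicon reads
#'
#' Keeps reads strictly longer than `min_length` whose maximum pairwise
#' identity to any query reference reaches `min_identity` (defaults: 300 bp
#' and 95%, the conventional genus-level screen). A k-mer prefilter (shared
#' 8-mer fraction) cheaply discards reads that cannot reach the identity
#' threshold before any alignment is attempted; reads surviving it are
#' scored by [best_hit()]. The rejection reason is recorded per read.
#'
#' @param reads named `DNAStringSet` of amplicon reads
#' @param refs named query references (the genus sequences screened for)
#' @param min_identity minimum percent identity to any reference
#' @param min_length reads must be strictly longer than this (nt)
#' @param kmer_min_share minimum fraction of read 8-mers present in the
#'   reference 8-mer pool for a read to proceed to alignment; reads at 95%
#'   identity share about two thirds of their 8-mers, unrelated random reads
#'   essentially none, so the default 0.15 is conservative
#' @return object of class `read_screen`: list with `retained` (a
#'   `DNAStringSet`) and `report` (read_id, length, best_ref, identity,
#'   retained, reason)
#' @export
screen_reads <- function(reads, refs, min_identity = 95.0,
                         min_length = 300L, kmer_min_share = 0.15) {
  if (length(refs) == 0L) stop("query reference set is empty", call. = FALSE)
  rs <- as_seq_chars(reads)
  ids <- names(rs)
  if (is.null(ids)) stop("reads must be named", call. = FALSE)
  k <- 8L
  ref_kmers <- unique(unlist(lapply(as_seq_chars(refs), function(r) {
    n <- nchar(r)
    if (n < k) character(0) else substring(r, 1:(n - k + 1L), k:n)
  }), use.names = FALSE))
  n <- length(rs)
  len <- nchar(rs)
  best_ref <- rep(NA_character_, n)
  identity <- rep(NA_real_, n)
  reason <- rep("", n)
  retained <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (len[i] <= min_length) {
      reason[i] <- "short"
      next
    }
    km <- substring(rs[i], 1:(len[i] - k + 1L), k:len[i])
    share <- mean(km %in% ref_kmers)
    if (share < kmer_min_share) {
      reason[i] <- "low_identity"
      next
    }
    bh <- best_hit(rs[[i]], refs)
    best_ref[i] <- bh$ref_id
    identity[i] <- bh$identity
    if (bh$identity >= min_identity) {
      retained[i] <- TRUE
    } else {
      reason[i] <- "low_identity"
    }
  }
  structure(list(
    retained = reads[retained],
    report = data.frame(read_id = ids, length = len, best_ref = best_ref,
                        identity = identity, retained = retained,
                        reason = reason, stringsAsFactors = FALSE)
  ), class = "read_screen")
}

#' @export
print.read_screen <- function(x, ...) {
  cat("read_screen:", sum(x$report$retained), "of", nrow(x$report),
      "reads retained\n")
  invisible(x)
}

#' Greedy centroid OTU clustering
#'
#' De-novo clustering at a fixed identity threshold (default 99%). Reads are
#' visited in descending length order (ties by id); the first read seeds
#' OTU 1 and each subsequent read joins the first existing centroid it
#' matches at or above the threshold, otherwise it seeds a new OTU. The
#' visit and centroid order are fully specified, so the clustering is
#' deterministic and input-order free.
#'
#' @param reads named `DNAStringSet` (reads of a single region)
#' @param threshold percent identity for membership
#' @return object of class `otu_set`: list with `otus` (per-OTU centroid and
#'   members), `membership` (read_id, otu_id, identity_to_centroid), and
#'   `threshold`
#' @export
cluster_otus <- function(reads, threshold = 99.0) {
  rs <- as_seq_chars(reads)
  if (length(rs) == 0L) stop("no reads to cluster", call. = FALSE)
  ids <- names(rs)
  ord <- order(-nchar(rs), ids)
  centroids <- character(0)
  centroid_ids <- character(0)
  member_of <- integer(length(rs))
  member_idy <- numeric(length(rs))
  names(member_of) <- names(member_idy) <- ids
  for (i in ord) {
    joined <- FALSE
    for (ci in seq_along(centroids)) {
      idy <- as.numeric(percent_identity(rs[[i]], centroids[[ci]], digits = NA))
      if (idy >= threshold) {
        member_of[i] <- ci
        member_idy[i] <- idy
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      centroids <- c(centroids, rs[[i]])
      centroid_ids <- c(centroid_ids, ids[i])
      member_of[i] <- length(centroids)
      member_idy[i] <- 100
    }
  }
  otus <- lapply(seq_along(centroids), function(ci) {
    list(otu_id = sprintf("OTU_%d", ci),
         centroid_id = centroid_ids[ci],
         centroid_seq = centroids[[ci]],
         member_ids = sort(ids[member_of == ci]))
  })
  structure(list(
    otus = otus,
    membership = data.frame(read_id = ids,
                            otu_id = sprintf("OTU_%d", member_of),
                            identity_to_centroid = round(member_idy, 1),
                            stringsAsFactors = FALSE),
    threshold = threshold
  ), class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat("otu_set:", length(x$otus), "OTU(s) from", nrow(x$membership),
      "reads at", x$threshold, "% identity\n")
  invisible(x)
}

#' Environment attribution of an OTU
#'
#' An OTU is assigned a single environment when more than
#' `majority_fraction` (default 50%) of its member reads share that origin;
#' two environments joined by `+` when exactly two categories tie for the
#' maximum count; and `"Unclassified"` otherwise (no majority and no
#' two-way tie, e.g. member fractions 45/35/20). The three outcomes are
#' exhaustive and mutually exclusive.
#'
#' @param categories character vector: the environment category of each
#'   member read
#' @param majority_fraction fraction a single category must exceed
#' @return the environment label
#' @export
#' @examples
#' attribute_environment(rep(c("Freshwater", "Soil"), c(6, 4)))  # Freshwater
#' attribute_environment(rep(c("Freshwater", "Soil"), c(5, 5)))  # tie
attribute_environment <- function(categories, majority_fraction = 0.5) {
  stopifnot(length(categories) > 0L, !anyNA(categories))
  counts <- table(categories)
  top <- max(counts)
  if (top / length(categories) > majority_fraction) {
    return(names(counts)[which.max(counts)])
  }
  at_max <- sort(names(counts)[counts == top])
  if (length(at_max) == 2L) {
    return(paste(at_max, collapse = "+"))
  }
  "Unclassified"
}

#' Per-OTU environment attribution table
#'
#' @param otu_set an `otu_set` from [cluster_otus()]
#' @param read_categories named character vector read_id -> environment
#'   category
#' @param majority_fraction see [attribute_environment()]
#' @return data.frame with one row per OTU: otu_id, centroid_id, n_members,
#'   environment_label, and per-category member counts
#' @export
otu_environment_table <- function(otu_set, read_categories,
                                  majority_fraction = 0.5) {
  stopifnot(inherits(otu_set, "otu_set"))
  cats <- sort(unique(unname(read_categories)))
  rows <- lapply(otu_set$otus, function(o) {
    mc <- read_categories[o$member_ids]
    if (anyNA(mc)) {
      stop("missing category for member(s) of ", o$otu_id, call. = FALSE)
    }
    counts <- table(factor(mc, levels = cats))
    cbind(data.frame(otu_id = o$otu_id, centroid_id = o$centroid_id,
                     n_members = length(o$member_ids),
                     environment_label =
                       attribute_environment(mc, majority_fraction),
                     stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(counts))))
  })
  do.call(rbind, rows)
}

#' Frequency of occurrence per environment category
#'
#' The number of samples positive for a clade in each category, divided by
#' the total number of samples of the category, as a percent. A sample is
#' positive when at least one retained read is assigned to the clade.
#' Categories with zero samples are reported as `NA` (undefined), never 0.
#'
#' @param samples sample table (sample_id, category, total_reads)
#' @param positives either a character vector of positive sample ids (single
#'   clade / genus level) or a data.frame with columns sample_id, clade
#' @return data.frame clade, category, n_samples, n_positive,
#'   freq_occurrence_pct
#' @export
frequency_of_occurrence <- function(samples, positives) {
  if (is.character(positives)) {
    positives <- if (length(positives) > 0L) {
      data.frame(sample_id = positives, clade = "all", stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = character(0), clade = character(0),
                 stringsAsFactors = FALSE)
    }
    clades <- "all"
  } else {
    stopifnot(all(c("sample_id", "clade") %in% names(positives)))
    clades <- sort(unique(positives$clade))
    if (length(clades) == 0L) clades <- "all"
  }
  unknown <- setdiff(positives$sample_id, samples$sample_id)
  if (length(unknown) > 0L) {
    stop("positive sample id not in sample table: ", unknown[1L], call. = FALSE)
  }
  cats <- unique(samples$category)
  out <- expand.grid(clade = clades, category = cats,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_samples <- vapply(out$category, function(cc) {
    sum(samples$category == cc)
  }, integer(1))
  out$n_positive <- mapply(function(k, cc) {
    sids <- samples$sample_id[samples$category == cc]
    length(unique(positives$sample_id[positives$clade == k &
                                        positives$sample_id %in% sids]))
  }, out$clade, out$category)
  out$freq_occurrence_pct <- ifelse(out$n_samples > 0L,
                                    100 * out$n_positive / out$n_samples,
                                    NA_real_)
  out[order(out$clade, out$category), , drop = FALSE]
}

#' Relative abundance per environment category
#'
#' The average, over positive samples only, of the clade's read count
#' divided by the sample's total reads, as a percent. Undefined (`NA`), not
#' 0, when a category has no positive samples; adding negative samples
#' leaves the value unchanged by construction.
#'
#' @param samples sample table (sample_id, category, total_reads)
#' @param counts data.frame with columns sample_id, clade, reads: retained
#'   read counts per sample and clade (absent rows mean zero reads)
#' @return data.frame clade, category, n_positive, rel_abundance_pct
#' @export
relative_abundance <- function(samples, counts) {
  stopifnot(all(c("sample_id", "clade", "reads") %in% names(counts)))
  m <- merge(counts, samples, by = "sample_id")
  if (nrow(m) < nrow(counts)) {
    stop("count rows refer to samples absent from the sample table",
         call. = FALSE)
  }
  if (any(m$reads > m$total_reads)) {
    stop("clade reads exceed total_reads for sample ",
         m$sample_id[which(m$reads > m$total_reads)[1L]], call. = FALSE)
  }
  m <- m[m$reads >= 1L, , drop = FALSE]
  clades <- sort(unique(counts$clade))
  cats <- unique(samples$category)
  out <- expand.grid(clade = clades, category = cats,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats <- mapply(function(k, cc) {
    sel <- m$clade == k & m$category == cc
    if (!any(sel)) return(c(0, NA_real_))
    c(sum(sel), mean(100 * m$reads[sel] / m$total_reads[sel]))
  }, out$clade, out$category)
  out$n_positive <- as.integer(stats[1L, ])
  out$rel_abundance_pct <- stats[2L, ]
  out[order(out$clade, out$category), , drop = FALSE]
}

#' Combined ecology indices from read assignments
#'
#' Convenience wrapper deriving both indices from per-read clade
#' assignments (e.g. the retained reads of [screen_reads()] joined to a
#' clade map of the references).
#'
#' @param samples sample table
#' @param assignments data.frame read_id, sample_id, clade for every
#'   retained read
#' @return data.frame clade, category, n_samples, n_positive,
#'   freq_occurrence_pct, rel_abundance_pct
#' @export
ecology_stats <- function(samples, assignments) {
  stopifnot(all(c("sample_id", "clade") %in% names(assignments)))
  counts <- stats::aggregate(list(reads = assignments$sample_id),
                             by = list(sample_id = assignments$sample_id,
                                       clade = assignments$clade),
                             FUN = length)
  freq <- frequency_of_occurrence(samples,
                                  counts[counts$reads >= 1L,
                                         c("sample_id", "clade")])
  ra <- relative_abundance(samples, counts)
  merge(freq, ra[, c("clade", "category", "rel_abundance_pct")],
        by = c("clade", "category"), all.x = TRUE)
}
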