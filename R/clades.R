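#' Species-level clade delimitation by single-linkage identity clustering
#'
#' Clades are the connected components of the graph whose vertices are the
#' sequences and whose edges join pairs with pairwise identity at or above
#' the species threshold (default 98.7%, the upper bound of the 98.65-98.7%
#' range used to discriminate bacterial species on 16S rRNA identity).
#' Single linkage is deliberate: a clade may contain pairs below the
#' threshold as long as a chain of above-threshold links connects them,
#' which is how heterogeneous clades (within-clade minima well below the
#' species cut) remain single clades.
#'
#' Clade labels are assigned by descending clade size, ties broken by the
#' lexicographically smallest member id, and are `A`, `B`, `C`, ...
#'
#' @param m symmetric identity matrix from [identity_matrix()]
#' @param threshold species-level percent identity threshold
#' @return object of class `clade_partition`: list with `clades` (named list
#'   of member id vectors), `membership` (named vector id -> label),
#'   `threshold_used`, `within_identity` (per-clade min/max), and
#'   `between_max` (largest between-clade identity)
#' @export
#' @examples
#' m <- matrix(c(100, 99, 97, 99, 100, 97.2, 97, 97.2, 100), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' delimit_clades(m, threshold = 98.7)$clades
delimit_clades <- function(m, threshold = 98.7) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("identity matrix must be symmetric", call. = FALSE)
  }
  ids <- rownames(m)
  n <- length(ids)
  adj <- m >= threshold
  diag(adj) <- TRUE
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cur <- cur + 1L
      queue <- v
      comp[v] <- cur
      while (length(queue) > 0L) {
        u <- queue[1L]; queue <- queue[-1L]
        nb <- which(adj[u, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  groups <- split(ids, comp)
  sizes <- lengths(groups)
  first_id <- vapply(groups, function(g) min(g), "")
  ord <- order(-sizes, first_id)
  groups <- lapply(groups[ord], sort)
  labels <- clade_labels(length(groups))
  names(groups) <- labels
  membership <- stats::setNames(rep(labels, lengths(groups)),
                                unlist(groups, use.names = FALSE))
  membership <- membership[ids]
  within <- do.call(rbind, lapply(labels, function(lb) {
    g <- groups[[lb]]
    sub <- m[g, g, drop = FALSE]
    off <- sub[upper.tri(sub)]
    data.frame(clade = lb, n = length(g),
               min_identity = if (length(off)) min(off) else NA_real_,
               max_identity = if (length(off)) max(off) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  between_max <- NA_real_
  if (length(groups) > 1L) {
    between_max <- max(vapply(seq_along(groups)[-1L], function(i) {
      max(vapply(seq_len(i - 1L), function(j) {
        max(m[groups[[i]], groups[[j]], drop = FALSE])
      }, numeric(1)))
    }, numeric(1)))
  }
  structure(list(clades = groups, membership = membership,
                 threshold_used = threshold, within_identity = within,
                 between_max = between_max),
            class = "clade_partition")
}

clade_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else c(LETTERS, paste0("Z", seq_len(n - 26L)))[seq_len(n)]
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("clade_partition:", length(x$clades), "clade(s) at threshold",
      x$threshold_used, "%\n")
  for (lb in names(x$clades)) {
    w <- x$within_identity[x$within_identity$clade == lb, ]
    cat(sprintf("  Clade %s (n=%d): %s%s\n", lb, length(x$clades[[lb]]),
                paste(utils::head(x$clades[[lb]], 4L), collapse = ", "),
                if (length(x$clades[[lb]]) > 4L) ", ..." else ""))
  }
  if (!is.na(x$between_max)) {
    cat("  max between-clade identity:", x$between_max, "%\n")
  }
  invisible(x)
}

#' Tabular view of a clade partition
#' @param partition a `clade_partition`
#' @return data.frame with columns id, clade
#' @export
clade_table <- function(partition) {
  stopifnot(inherits(partition, "clade_partition"))
  data.frame(id = names(partition$membership),
             clade = unname(partition$membership),
             stringsAsFactors = FALSE)
}
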