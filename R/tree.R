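#' Neighbor-joining tree from an identity-derived distance matrix
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix (here,
#' `100 - percent identity`, with no evolutionary-model correction - the
#' desk-scale stand-in for likelihood tree inference). The joining itself is
#' delegated to [ape::nj()]; negative branch lengths, which NJ can produce
#' on non-additive matrices, are clamped to zero with the deficit moved to
#' the sister branch so path lengths are preserved as far as possible.
#'
#' @param d symmetric numeric matrix with zero diagonal and taxon names as
#'   dimnames, or a `dist` object
#' @return an `ape::phylo` tree (unrooted for >= 3 taxa)
#' @export
#' @examples
#' m <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' write_newick(nj_tree(m))  # "(A:2.000000,B:2.000000);"
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-8)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
               edge.length = rep(d[1L, 2L] / 2, 2L),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tr)
}

# move each negative branch's deficit to its sister branch, then clamp
clamp_negative_branches <- function(tr, max_pass = 10L) {
  for (pass in seq_len(max_pass)) {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    for (e in neg) {
      if (tr$edge.length[e] >= 0) next
      parent <- tr$edge[e, 1L]
      sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
      if (length(sibs) > 0L) {
        sib <- sibs[which.max(tr$edge.length[sibs])]
        tr$edge.length[sib] <- tr$edge.length[sib] + tr$edge.length[e]
      }
      tr$edge.length[e] <- 0
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Distance matrix from percent identities
#' @param identity symmetric percent-identity matrix from [identity_matrix()]
#' @return distance matrix `100 - identity` with zero diagonal
#' @export
identity_to_distance <- function(identity) {
  d <- 100 - identity
  diag(d) <- 0
  d
}
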