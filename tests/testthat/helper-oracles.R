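# Independent oracles used to check the implementation. Deliberately naive:
# textbook dynamic programming for ends-free alignment score, Hamming
# identity, exhaustive clique-cover enumeration, closed-form 3-taxon NJ.

# maximal ends-free alignment score: match +2, mismatch -1, gap -2 per
# position, leading/trailing gaps free
oracle_overlap_score <- function(a, b) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  D <- matrix(0, n + 1L, m + 1L)  # free leading gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (A[i] == B[j]) 2 else -1
      D[i + 1L, j + 1L] <- max(D[i, j] + sub,
                               D[i, j + 1L] - 2,
                               D[i + 1L, j] - 2)
    }
  }
  max(D[n + 1L, ], D[, m + 1L])  # free trailing gaps
}

# identity of two gap-free equal-length strings
oracle_hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

# minimum number of cliques covering all vertices of an undirected graph
# given as an adjacency matrix (exhaustive branch and bound)
oracle_min_clique_cover <- function(adj) {
  n <- nrow(adj)
  best <- n
  assign_next <- function(v, groups) {
    if (length(groups) >= best) return(invisible())
    if (v > n) {
      best <<- min(best, length(groups))
      return(invisible())
    }
    for (gi in seq_along(groups)) {
      if (all(adj[v, groups[[gi]]])) {
        g2 <- groups
        g2[[gi]] <- c(g2[[gi]], v)
        assign_next(v + 1L, g2)
      }
    }
    assign_next(v + 1L, c(groups, list(v)))
  }
  assign_next(1L, list())
  best
}

# closed-form neighbor-joining branch lengths for three taxa
oracle_nj3 <- function(dab, dac, dbc) {
  c(a = (dab + dac - dbc) / 2,
    b = (dab + dbc - dac) / 2,
    c = (dac + dbc - dab) / 2)
}

# minimum mismatches of a degenerate probe target against a gene window,
# by exhaustive expansion of all degenerate positions
oracle_probe_mismatches <- function(target, gene_window) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  tc <- strsplit(target, "")[[1L]]
  gc <- strsplit(gene_window, "")[[1L]]
  expansions <- Reduce(function(acc, ch) {
    unlist(lapply(acc, function(p) paste0(p, sets[[ch]])))
  }, tc, accumulate = FALSE, init = "")
  g_expansions <- Reduce(function(acc, ch) {
    unlist(lapply(acc, function(p) paste0(p, sets[[ch]])))
  }, gc, init = "")
  min(vapply(expansions, function(e) {
    ec <- strsplit(e, "")[[1L]]
    min(vapply(g_expansions, function(ge) {
      sum(ec != strsplit(ge, "")[[1L]])
    }, numeric(1)))
  }, numeric(1)))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, k) {
  chars <- strsplit(s, "")[[1L]]
  pos <- sample(length(chars), k)
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, "")
  paste(chars, collapse = "")
}
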