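test_that("ends-free alignment is optimal against exhaustive DP on short strings", {
  set.seed(42)
  for (i in 1:25) {
    a <- random_seq(8)
    b <- random_seq(sample(6:10, 1))
    aln <- global_align(a, b)
    expect_equal(aln$score, oracle_overlap_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment handles identity and terminal gaps as specified", {
  aln <- global_align("ACGT", "ACGT")
  expect_equal(aln$pattern, "ACGT")
  expect_equal(aln$subject, "ACGT")
  # one terminal overhang, un-penalized: identity computed on the overlap
  expect_equal(as.numeric(percent_identity("ACGTACGT", "ACGTACG")), 100)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("percent identity follows the stated definition", {
  expect_equal(as.numeric(percent_identity("ACGTACGT", "ACGTACGT")), 100)
  # one internal substitution in 1000 nt
  a <- paste0(strrep("AC", 250), "T", strrep("GT", 250))
  b <- paste0(strrep("AC", 250), "A", strrep("GT", 250))
  expect_equal(as.numeric(percent_identity(a, b)), 99.9)
  expect_equal(attr(percent_identity(a, b), "aligned_columns"), 501L * 2L - 1L)
  # degenerate positions match iff expansion sets intersect
  expect_equal(as.numeric(percent_identity(paste0("YY", strrep("ACGT", 5)),
                                           paste0("CT", strrep("ACGT", 5)))), 100)
  expect_lt(as.numeric(percent_identity(paste0("YA", strrep("ACGT", 5)),
                                        paste0("AA", strrep("ACGT", 5)))), 100)
})

test_that("identity equals Hamming identity on gap-free equal-length pairs", {
  set.seed(7)
  for (i in 1:10) {
    a <- random_seq(300)
    b <- mutate_seq(a, sample(1:12, 1))
    expect_equal(as.numeric(percent_identity(a, b, digits = NA)),
                 oracle_hamming_identity(a, b), tolerance = 1e-10)
  }
})

test_that("identity matrices are symmetric, reflexive and order-free", {
  g <- small_genus()
  m <- identity_matrix(g$sequences[1:5])
  expect_true(all(diag(m) == 100))
  expect_equal(m, t(m))
  s3 <- Biostrings::DNAStringSet(setNames(rep("ACGTACGTACGT", 3),
                                          c("x", "y", "z")))
  expect_true(all(identity_matrix(s3) == 100))
})

test_that("single-linkage clade delimitation matches its definition", {
  ids <- c("A", "B", "C")
  m <- matrix(100, 3, 3, dimnames = list(ids, ids))
  m["A", "B"] <- m["B", "A"] <- 99.0
  m["A", "C"] <- m["C", "A"] <- 97.0
  m["B", "C"] <- m["C", "B"] <- 97.2
  p <- delimit_clades(m, threshold = 98.7)
  expect_equal(unname(lapply(p$clades, sort)), list(c("A", "B"), "C"))
  # threshold 0: everything chained into one clade
  expect_length(delimit_clades(m, threshold = 0)$clades, 1L)
  # chaining: A-B and B-C linked, A-C not -> still one clade (single linkage)
  m["B", "C"] <- m["C", "B"] <- 99.1
  expect_length(delimit_clades(m, threshold = 98.7)$clades, 1L)
})

test_that("raising the threshold never merges clades", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 8
    ids <- paste0("s", 1:n)
    m <- matrix(100, n, n, dimnames = list(ids, ids))
    vals <- runif(n * (n - 1) / 2, 90, 100)
    m[upper.tri(m)] <- vals
    m <- pmax(m, t(m)); m[lower.tri(m)] <- t(m)[lower.tri(m)]
    lo <- delimit_clades(m, threshold = 95)
    hi <- delimit_clades(m, threshold = 99)
    expect_gte(length(hi$clades), length(lo$clades))
    # every high-threshold clade sits inside one low-threshold clade
    for (g in hi$clades) {
      parents <- unique(lo$membership[g])
      expect_length(parents, 1L)
    }
  }
})

test_that("partition of a synthetic genus recovers the true clades", {
  fg <- full_genus()
  p <- delimit_clades(fg$matrix, threshold = 98.7)
  expect_length(p$clades, 5L)
  truth <- setNames(fg$genus$truth$clade, fg$genus$truth$id)
  for (members in p$clades) {
    expect_length(unique(truth[members]), 1L)
  }
  # label order invariant to input order
  perm <- sample(length(fg$genus$sequences))
  p2 <- delimit_clades(fg$matrix[perm, perm], threshold = 98.7)
  expect_equal(lapply(p$clades, sort), lapply(p2$clades, sort))
})
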