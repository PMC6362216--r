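test_that("the genus screen applies the length and identity rules", {
  g <- small_genus()
  refs <- g$sequences
  ref1 <- as.character(refs)[[1]]
  set.seed(10)
  reads <- Biostrings::DNAStringSet(c(
    perfect250 = substr(ref1, 100, 349),             # 250 nt: too short
    good400 = mutate_seq(substr(ref1, 100, 499), 12),  # 400 nt at 97%
    far400 = mutate_seq(substr(ref1, 100, 499), 36),   # 400 nt at 91%
    junk = random_seq(400)))
  sc <- screen_reads(reads, refs)
  rep <- sc$report
  expect_equal(rep$retained, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(rep$reason[rep$read_id == "perfect250"], "short")
  expect_equal(rep$reason[rep$read_id == "far400"], "low_identity")
  expect_equal(rep$reason[rep$read_id == "junk"], "low_identity")
  expect_equal(names(sc$retained), "good400")
  # idempotent and order-free
  sc2 <- screen_reads(rev(reads), refs)
  expect_setequal(names(sc2$retained), names(sc$retained))
  sc3 <- screen_reads(sc$retained, refs)
  expect_equal(names(sc3$retained), names(sc$retained))
})

test_that("greedy OTU clustering is deterministic and respects the threshold", {
  a <- strrep("ACGT", 25)
  reads <- Biostrings::DNAStringSet(c(r1 = a, r2 = a))
  expect_length(cluster_otus(reads)$otus, 1L)
  set.seed(4)
  b <- mutate_seq(a, 5)  # 95% identity
  expect_length(cluster_otus(Biostrings::DNAStringSet(c(r1 = a, r2 = b)),
                             threshold = 99)$otus, 2L)
  expect_length(cluster_otus(Biostrings::DNAStringSet(c(r1 = a, r2 = b)),
                             threshold = 94)$otus, 1L)
})

test_that("greedy clustering respects the exhaustive clique-cover bound on tiny sets", {
  set.seed(77)
  threshold <- 99
  for (rep in 1:10) {
    tmpl <- replicate(2, random_seq(80))
    reads <- Biostrings::DNAStringSet(setNames(vapply(1:8, function(i) {
      mutate_seq(tmpl[[sample(2, 1)]], sample(0:2, 1))
    }, ""), sprintf("r%02d", 1:8)))
    oset <- cluster_otus(reads, threshold = threshold)
    # every member sits at >= threshold from its centroid (always asserted)
    expect_true(all(oset$membership$identity_to_centroid >= threshold))
    # greedy count can never beat the optimal clique cover
    ids <- as.character(reads)
    adj <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j) {
      as.numeric(percent_identity(ids[[i]], ids[[j]], digits = NA)) >= threshold
    }))
    diag(adj) <- TRUE
    expect_gte(length(oset$otus), oracle_min_clique_cover(adj))
  }
})

test_that("OTU count is non-increasing as the threshold decreases", {
  g <- small_genus()
  set.seed(5)
  reads <- Biostrings::DNAStringSet(setNames(vapply(1:12, function(i) {
    mutate_seq(substr(as.character(g$sequences)[[sample(9, 1)]], 100, 300),
               sample(0:3, 1))
  }, ""), sprintf("r%02d", 1:12)))
  n_hi <- length(cluster_otus(reads, threshold = 99.5)$otus)
  n_md <- length(cluster_otus(reads, threshold = 99)$otus)
  n_lo <- length(cluster_otus(reads, threshold = 95)$otus)
  expect_gte(n_hi, n_md)
  expect_gte(n_md, n_lo)
})

test_that("environment attribution implements the three exhaustive rules", {
  expect_equal(attribute_environment(rep(c("Freshwater", "Soil"), c(6, 4))),
               "Freshwater")
  expect_equal(attribute_environment(rep(c("Freshwater", "Soil"), c(5, 5))),
               "Freshwater+Soil")
  expect_equal(attribute_environment(rep(c("Freshwater", "Soil", "Seawater"),
                                         c(4, 3, 3))), "Unclassified")
  expect_equal(attribute_environment(rep(c("Seawater", "Soil", "Plants"),
                                         c(4, 4, 2))), "Seawater+Soil")
  expect_equal(attribute_environment("Soil"), "Soil")
})

test_that("frequency of occurrence is positives over category size", {
  samples <- data.frame(sample_id = sprintf("s%02d", 1:60),
                        category = "Freshwater", total_reads = 1000)
  f <- frequency_of_occurrence(samples, c("s01", "s02", "s03"))
  expect_equal(f$freq_occurrence_pct, 5.0)
  expect_equal(f$n_positive, 3L)
  f0 <- frequency_of_occurrence(samples, character(0))
  expect_equal(f0$freq_occurrence_pct, 0.0)
  expect_error(frequency_of_occurrence(samples, "not_a_sample"), "sample")
})

test_that("relative abundance averages over positive samples only", {
  samples <- data.frame(sample_id = c("p1", "p2", "n1", "n2"),
                        category = "Freshwater",
                        total_reads = c(100000L, 10000L, 5000L, 5000L))
  counts <- data.frame(sample_id = c("p1", "p2"), clade = "A",
                       reads = c(50L, 4L))
  ra <- relative_abundance(samples, counts)
  expect_equal(ra$rel_abundance_pct, mean(c(0.05, 0.04)))
  # adding genus-negative samples leaves the value unchanged
  more <- rbind(samples, data.frame(sample_id = "n3", category = "Freshwater",
                                    total_reads = 7000L))
  expect_equal(relative_abundance(more, counts)$rel_abundance_pct,
               ra$rel_abundance_pct)
  # no positive samples: undefined, not zero
  ra0 <- relative_abundance(samples, data.frame(sample_id = "p1", clade = "A",
                                                reads = 0L))
  expect_true(is.na(ra0$rel_abundance_pct))
  expect_error(relative_abundance(samples,
                                  data.frame(sample_id = "p2", clade = "A",
                                             reads = 20000L)), "exceed")
})

test_that("neighbor joining matches closed forms and preserves additive distances", {
  # two taxa: two branches of d/2
  m2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(m2)
  expect_equal(sort(t2$edge.length), c(2, 2))
  # three taxa: closed-form three-point branch lengths
  ids <- c("a", "b", "c")
  m3 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  m3["a", "b"] <- m3["b", "a"] <- 5
  m3["a", "c"] <- m3["c", "a"] <- 7
  m3["b", "c"] <- m3["c", "b"] <- 8
  t3 <- nj_tree(m3)
  want <- oracle_nj3(5, 7, 8)
  got <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(got[ids], c(a = want[["a"]], b = want[["b"]], c = want[["c"]]))
  # any additive 5-taxon matrix is reproduced exactly
  set.seed(31)
  for (rep in 1:5) {
    tr <- ape::rtree(5, br = function(n) runif(n, 0.5, 3))
    tr$tip.label <- paste0("t", 1:5)
    d <- ape::cophenetic.phylo(tr)
    out <- nj_tree(d[paste0("t", 1:5), paste0("t", 1:5)])
    d2 <- ape::cophenetic.phylo(out)
    expect_equal(d2[rownames(d), colnames(d)], d, tolerance = 1e-8)
    expect_true(all(out$edge.length >= 0))
  }
  bad <- m3; bad["a", "b"] <- 1
  expect_error(nj_tree(bad), "symmetric")
})
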