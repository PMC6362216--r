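test_that("the generator is fully deterministic under a fixed seed", {
  spec <- genus_spec(n_clades = 2, n_per_clade = 2, seq_length = 400,
                     variable_blocks = data.frame(start = 50L, end = 120L),
                     seed = 5)
  g1 <- generate_reference_genus(spec)
  g2 <- generate_reference_genus(spec)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$truth, g2$truth)

  ch1 <- generate_chimeras(g1, n = 4, margin = 60, seed = 9)
  ch2 <- generate_chimeras(g1, n = 4, margin = 60, seed = 9)
  expect_identical(as.character(ch1$sequences), as.character(ch2$sequences))
})

test_that("degenerate specs behave as documented", {
  # single clade, zero within-divergence: all members identical
  g <- generate_reference_genus(genus_spec(
    n_clades = 1, n_per_clade = 4, seq_length = 300, within_divergence = 0,
    variable_blocks = data.frame(start = 50L, end = 100L), seed = 2))
  expect_length(unique(as.character(g$sequences)), 1L)
  # rates implying >25% per-block divergence are refused
  expect_error(generate_reference_genus(genus_spec(
    n_clades = 2, n_per_clade = 2, seq_length = 300,
    within_divergence = 5, between_root_divergence = c(9, 10),
    variable_blocks = data.frame(start = 1L, end = 30L), seed = 1)),
    "25%")
  # within must stay below between
  expect_error(genus_spec(within_divergence = 3,
                          between_root_divergence = c(1, 1.5)), "divergence")
})

test_that("realized identity structure matches the spec bounds", {
  fg <- full_genus()
  m <- fg$matrix
  truth <- fg$genus$truth
  same <- outer(truth$clade, truth$clade, "==")
  up <- upper.tri(m)
  within <- m[up & same]
  between <- m[up & !same]
  expect_gte(mean(within >= 98.3), 0.95)
  expect_gte(mean(between <= 98.5), 0.95)
  expect_lt(max(between), min(within) + 2)  # regimes clearly separated
})

test_that("chimeras are recorded with distinct-clade parents and valid breakpoints", {
  g <- small_genus()
  ch <- generate_chimeras(g, n = 10, margin = 120, seed = 3)
  expect_length(ch$sequences, 10L)
  expect_true(all(ch$truth$clade_a != ch$truth$clade_b))
  expect_true(all(ch$truth$breakpoint >= 120 & ch$truth$breakpoint <= 480))
  # each chimera is exactly prefix(parent_a) + suffix(parent_b)
  ss <- as.character(g$sequences)
  for (i in seq_len(nrow(ch$truth))) {
    tr <- ch$truth[i, ]
    expect_equal(as.character(ch$sequences)[[tr$id]],
                 paste0(substr(ss[[tr$parent_a]], 1, tr$breakpoint),
                        substr(ss[[tr$parent_b]], tr$breakpoint + 1, 600)))
  }
  # single-clade reference sets are refused
  g1 <- generate_reference_genus(genus_spec(
    n_clades = 1, n_per_clade = 3, seq_length = 300,
    variable_blocks = data.frame(start = 50L, end = 100L), seed = 2))
  expect_error(generate_chimeras(g1, n = 2, margin = 60, seed = 1), "2 clades")
  expect_error(generate_chimeras(g, n = 2, margin = 300, seed = 1), "margin")
})

test_that("sample generation respects occupancy and records complete truth", {
  g <- small_genus()
  # windows must fit the 600 nt reference
  win <- data.frame(name = c("V1V2", "V4V6"), start = c(40L, 350L),
                    end = c(180L, 520L))
  base <- list(samples_per_category = c(Freshwater = 6L, Soil = 4L),
               total_reads_range = c(500L, 800L),
               abundance_bounds = c(0.01, 0.05),
               background_per_sample = 3L,
               region_mix = c(V1V2 = 0.5, V4V6 = 0.5),
               read_length_range = c(120L, 160L),
               windows = win)
  # zero occupancy: all samples genus-negative
  sp0 <- do.call(sample_spec, c(base, list(occupancy = 0)))
  sim0 <- generate_sample_reads(g, sp0, seed = 4)
  expect_true(all(!sim0$truth$presence$present))
  expect_true(all(sim0$truth$reads$origin == "background"))

  sp1 <- do.call(sample_spec, c(base, list(occupancy = 1)))
  sim1 <- generate_sample_reads(g, sp1, seed = 4)
  expect_true(all(sim1$truth$presence$present))
  # truth is complete: every emitted read maps to a recorded origin
  expect_setequal(names(sim1$reads), sim1$truth$reads$read_id)
  expect_equal(S4Vectors::mcols(sim1$reads)$sample_id,
               sim1$truth$reads$sample_id)
  # per-sample per-clade emitted read counts agree with the presence table
  emitted <- table(sim1$truth$reads$sample_id[sim1$truth$reads$origin != "background"],
                   sim1$truth$reads$origin[sim1$truth$reads$origin != "background"])
  pres <- sim1$truth$presence
  for (i in seq_len(nrow(pres))) {
    got <- if (pres$sample_id[i] %in% rownames(emitted) &&
               pres$clade[i] %in% colnames(emitted)) {
      emitted[pres$sample_id[i], pres$clade[i]]
    } else 0L
    expect_equal(unname(got), pres$n_reads[i])
  }
  # a window beyond the reference is refused
  badwin <- data.frame(name = "V9", start = 550L, end = 700L)
  spbad <- do.call(sample_spec, c(base[setdiff(names(base), c("windows", "region_mix"))],
                                  list(windows = badwin,
                                       region_mix = c(V9 = 1),
                                       occupancy = 1)))
  expect_error(generate_sample_reads(g, spbad, seed = 1), "window")
})

test_that("expected genus read counts follow the abundance fraction", {
  g <- small_genus()
  win <- data.frame(name = "V4V6", start = 350L, end = 520L)
  sp <- sample_spec(samples_per_category = c(Freshwater = 30L),
                    occupancy = 1,
                    abundance_bounds = c(0.00499, 0.005),
                    total_reads_range = c(10000L, 10000L),
                    background_per_sample = 0L,
                    region_mix = c(V4V6 = 1),
                    read_length_range = c(120L, 160L),
                    windows = win)
  sim <- generate_sample_reads(g, sp, seed = 8)
  counts <- sim$truth$presence$n_reads[sim$truth$presence$clade == "A"]
  # Binomial(10000, ~0.005): mean 50, sd ~7; the mean of 30 samples
  # stays within 5 sd of expectation
  expect_gt(mean(counts), 50 - 5 * 7 / sqrt(30))
  expect_lt(mean(counts), 50 + 5 * 7 / sqrt(30))
})
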