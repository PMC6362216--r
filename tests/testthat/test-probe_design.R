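test_that("GC fraction weights degenerate symbols by expected content", {
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("CCGTTTGCCACTAACGAC"), 10 / 18)
  expect_equal(gc_fraction("YCTGAAGCAAGCTCCAGC"), 10.5 / 18)
  expect_equal(gc_fraction("ATWN"), 0.5 / 4)
  expect_equal(gc_fraction("BDHV"), (2 / 3 + 1 / 3 + 1 / 3 + 2 / 3) / 4)
})

test_that("melting temperature is monotone in GC and length and guards its regime", {
  # increasing GC at fixed length
  tm_low <- melting_temperature(paste0(strrep("AT", 7), "ATAT"))
  tm_hi <- melting_temperature(paste0(strrep("GC", 7), "ATAT"))
  expect_gt(tm_hi, tm_low)
  # increasing length at fixed GC fraction
  expect_gt(melting_temperature(strrep("ACGT", 6)),
            melting_temperature(strrep("ACGT", 4)))
  expect_error(melting_temperature("ACGTACGTACGTA"), "14")
  # rounding is half-away-from-zero to one decimal
  expect_equal(melting_temperature(strrep("ACGT", 5)),
               round(69.3 + 0.41 * 50 - 650 / 20, 1))
})

test_that("probe objects validate their sequence and recompute Tm", {
  p <- probe("MegVene_95", "CCGTTTGCCACTAACGAC", "Clade C")
  expect_equal(p$tm, melting_temperature(p$seq))
  expect_equal(p$length, 18L)
  expect_error(probe("short", "ACGTACGTACGT"), "15")
  expect_error(probe("bad", "ACGTACGTACGTACGTZZ"), "non-IUPAC")
})

test_that("probe matching equals exhaustive degenerate expansion on small cases", {
  set.seed(19)
  for (rep in 1:6) {
    gene <- random_seq(40)
    start <- sample(1:20, 1)
    site <- substr(gene, start, start + 15)
    chars <- strsplit(site, "")[[1]]
    deg_pos <- sample(16, sample(0:2, 1))
    for (dp in deg_pos) {
      chars[dp] <- sample(c("R", "Y", "N", "S", "W"), 1)
    }
    target <- paste(chars, collapse = "")
    pseq <- megascreen:::revcomp(target)
    hits1 <- probe_matches(pseq, gene, max_mismatch = 1)
    for (off in seq_len(nchar(gene) - 15)) {
      mm <- oracle_probe_mismatches(target, substr(gene, off, off + 15))
      in_hits <- off %in% hits1$position
      expect_equal(in_hits, mm <= 1, info = paste("rep", rep, "off", off))
      if (in_hits) {
        expect_equal(hits1$mismatches[hits1$position == off], mm)
      }
    }
  }
})

test_that("probe matching applies the reverse-complement and expansion rules", {
  g <- small_genus()
  gene <- g$ancestor
  window <- substr(gene, 101, 120)
  pseq <- megascreen:::revcomp(window)
  hit <- probe_matches(pseq, gene, 0)
  expect_true(101 %in% hit$position)
  # one substituted base: invisible at m=0, found at m=1
  chars <- strsplit(pseq, "")[[1]]
  chars[10] <- setdiff(c("A", "C", "G", "T"), chars[10])[1]
  mut <- paste(chars, collapse = "")
  expect_false(101 %in% probe_matches(mut, gene, 0)$position)
  expect_true(101 %in% probe_matches(mut, gene, 1)$position)
  # degenerate target position: Y matches C or T, mismatches A
  w_c <- paste0("C", strrep("ACGT", 4))          # window starting with C
  w_a <- paste0("A", strrep("ACGT", 4))          # window starting with A
  target_y <- paste0("Y", strrep("ACGT", 4))     # Y at the first position
  probe_y <- megascreen:::revcomp(target_y)
  expect_equal(probe_matches(probe_y, w_c, 0)$position, 1L)
  expect_equal(nrow(probe_matches(probe_y, w_a, 0)), 0L)
  expect_equal(probe_matches(probe_y, w_a, 1)$mismatches, 1L)
})

test_that("specificity hit sets are nested across mismatch levels", {
  g <- small_genus()
  ss <- as.character(g$sequences)
  site <- substr(ss[[1]], 66, 86)
  p <- probe("test_66", megascreen:::revcomp(site))
  rep <- specificity_screen(p, g$sequences[1:3], g$sequences[4:9])
  expect_lte(rep$levels$m0$target_hits, rep$levels$m1$target_hits)
  expect_lte(rep$levels$m0$nontarget_hits, rep$levels$m1$nontarget_hits)
  expect_true(all(rep$levels$m0$nontarget_ids %in% rep$levels$m1$nontarget_ids))
  # empty non-target set: 0/0
  rep0 <- specificity_screen(p, g$sequences[1:3], Biostrings::DNAStringSet())
  expect_equal(rep0$levels$m0$nontarget_hits, 0L)
  expect_error(specificity_screen(p, g$sequences[1:3], g$sequences[3:5]),
               "disjoint")
})

test_that("probe design separates a designable clade and diagnoses impossible ones", {
  fg <- full_genus()
  g <- fg$genus
  ss <- as.character(g$sequences)
  cand <- design_probes(ss[g$truth$clade == "D"], ss[g$truth$clade != "D"],
                        g$ancestor, group_name = "cladeD")
  expect_gt(nrow(cand), 0)
  top <- cand[1, ]
  expect_equal(top$hits_target_m0, sum(g$truth$clade == "D"))
  expect_equal(top$hits_nontarget_m0, 0L)
  # independent check through the screening path
  srep <- specificity_screen(probe(top$name, top$seq),
                             g$sequences[g$truth$clade == "D"],
                             g$sequences[g$truth$clade != "D"])
  expect_equal(srep$levels$m0$target_hits, sum(g$truth$clade == "D"))
  expect_equal(srep$levels$m0$nontarget_hits, 0L)
  # probe names encode the 5' position of the target site on the reference
  pos <- as.integer(sub(".*_", "", top$name))
  hits <- probe_matches(top$seq, g$ancestor, 1)
  expect_true(pos %in% hits$position || nrow(hits) == 0L)
  # identical targets and non-targets: empty list with diagnostic
  same <- setNames(rep(substr(g$ancestor, 1, 1400), 4), paste0("t", 1:4))
  e <- design_probes(same[1:2], same[3:4], g$ancestor)
  expect_equal(nrow(e), 0L)
  expect_match(attr(e, "diagnostic"), "no candidate")
})

test_that("a genus-level probe designed against background hits every member", {
  fg <- full_genus()
  g <- fg$genus
  set.seed(9)
  bg <- setNames(vapply(1:5, function(i) megascreen:::random_dna(1400, 0.55), ""),
                 paste0("bg", 1:5))
  cand <- design_probes(as.character(g$sequences), bg, g$ancestor,
                        group_name = "genus")
  expect_gt(nrow(cand), 0)
  expect_equal(cand$hits_target_m0[1], length(g$sequences))
  expect_equal(cand$hits_nontarget_m0[1], 0L)
})
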