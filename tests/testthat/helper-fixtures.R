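# Shared fixtures, built once per test run and cached.

# compact 3-clade genus (600 nt) for cheap unit tests
small_blocks <- function() {
  data.frame(start = c(60L, 200L, 400L), end = c(110L, 260L, 460L))
}

small_genus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_reference_genus(genus_spec(
        n_clades = 3L, n_per_clade = 3L, seq_length = 600L,
        variable_blocks = small_blocks(), seed = 101L))
    }
    cache
  }
})

# a well-separated 3-clade genus for chimera scans: with only 600 nt the
# per-half divergence is noisy, so clade roots sit at the top of the
# between-species band to keep both halves of any chimera in the
# detectable regime
chimera_genus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_reference_genus(genus_spec(
        n_clades = 3L, n_per_clade = 3L, seq_length = 600L,
        between_root_divergence = c(1.75, 2.5),
        variable_blocks = small_blocks(), seed = 102L))
    }
    cache
  }
})

# full-size default genus plus its unrounded identity matrix
full_genus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_reference_genus(genus_spec(seed = 11L))
      m <- identity_matrix(g$sequences, digits = NA)
      cache <<- list(genus = g, matrix = m)
    }
    cache
  }
})

# interval of breakpoints equivalent to the recorded truth: positions around
# the cut where the two parents agree (cutting anywhere there yields the
# same chimera)
breakpoint_interval <- function(genus, truth_row) {
  ss <- as.character(genus$sequences)
  a <- strsplit(ss[[truth_row$parent_a]], "")[[1L]]
  b <- strsplit(ss[[truth_row$parent_b]], "")[[1L]]
  eq <- a == b
  lo <- truth_row$breakpoint
  while (lo > 1L && eq[lo]) lo <- lo - 1L
  hi <- truth_row$breakpoint
  while (hi < length(a) && eq[hi + 1L]) hi <- hi + 1L
  c(lo, hi)
}
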