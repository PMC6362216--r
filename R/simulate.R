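#' Specification of a clade-structured synthetic 16S genus
#'
#' The generator emulates the identity structure of a species-rich
#' endosymbiont genus: one random ancestor, one root per clade mutated away
#' from the ancestor, and members mutated from their clade root.
#' Hypervariable blocks mutate faster than the conserved backbone
#' (default 5:1), reproducing the conserved-vs-hypervariable architecture of
#' the 16S gene. Mutations are substitutions only, so pairwise identity
#' arithmetic and chimera breakpoints stay exact.
#'
#' Divergences are percent expected pairwise divergence. Clade roots draw
#' their divergence from the ancestor uniformly in `between_root_divergence`,
#' so between-clade pairwise divergence is (approximately) the sum of two
#' such draws: the default `[1.0, 1.75]` realizes between-clade divergence
#' in roughly `[2.0, 3.5]`%, keeping clades separable at a 98.7% species
#' threshold under binomial noise while staying inside a realistic
#' between-species band. Within-clade pairwise divergence defaults to 1.0%
#' (members sit `within_divergence/2` from their root).
#'
#' @param n_clades number of species-level clades (default 5)
#' @param n_per_clade members generated per clade
#' @param seq_length full gene length in nt
#' @param within_divergence expected within-clade pairwise divergence, percent
#' @param between_root_divergence length-2 range for per-clade root-to-ancestor
#'   divergence, percent
#' @param variable_blocks data.frame (start, end) of hypervariable blocks on
#'   the ancestor coordinate system; defaults to nine V-like blocks
#' @param variable_rate_ratio substitution-rate ratio variable:conserved
#' @param gc ancestor GC fraction
#' @param seed integer seed; the generator is fully deterministic given it
#' @return object of class `genus_spec`
#' @export
genus_spec <- function(n_clades = 5L, n_per_clade = 4L, seq_length = 1400L,
                       within_divergence = 1.0,
                       between_root_divergence = c(1.0, 1.75),
                       variable_blocks = default_variable_blocks(),
                       variable_rate_ratio = 5,
                       gc = 0.5, seed = 1L) {
  stopifnot(n_clades >= 1L, n_per_clade >= 1L, seq_length >= 100L)
  if (within_divergence >= 2 * min(between_root_divergence)) {
    stop("within-clade divergence must be below between-clade divergence",
         call. = FALSE)
  }
  if (any(variable_blocks$end > seq_length)) {
    stop("variable blocks must lie within [1, seq_length]", call. = FALSE)
  }
  validate_windows(cbind(name = "v", variable_blocks))
  structure(list(n_clades = as.integer(n_clades),
                 n_per_clade = as.integer(n_per_clade),
                 seq_length = as.integer(seq_length),
                 within_divergence = within_divergence,
                 between_root_divergence = between_root_divergence,
                 variable_blocks = variable_blocks,
                 variable_rate_ratio = variable_rate_ratio,
                 gc = gc, seed = as.integer(seed)),
            class = "genus_spec")
}

#' @rdname genus_spec
#' @export
default_variable_blocks <- function() {
  data.frame(start = c(69L, 137L, 433L, 576L, 822L, 986L, 1117L, 1243L),
             end   = c(99L, 242L, 497L, 682L, 879L, 1043L, 1173L, 1294L))
}

# per-position substitution probability vector realizing mean divergence d
# (percent), with variable blocks mutating `ratio` times faster
.position_rates <- function(d, spec) {
  w <- rep(1, spec$seq_length)
  for (i in seq_len(nrow(spec$variable_blocks))) {
    w[spec$variable_blocks$start[i]:spec$variable_blocks$end[i]] <-
      spec$variable_rate_ratio
  }
  rate <- (d / 100) * w / mean(w)
  if (max(rate) > 0.25) {
    stop("implied per-block divergence exceeds 25%; identity model breaks down",
         call. = FALSE)
  }
  rate
}

.mutate <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
  }
  chars
}

#' Generate a clade-structured reference genus with ground truth
#'
#' @param spec a [genus_spec()]
#' @return object of class `genus_sim`: list with `sequences` (named
#'   `DNAStringSet`), `ancestor` (character, the shared coordinate system),
#'   `truth` (data.frame id, clade), and `spec`
#' @export
#' @examples
#' g <- generate_reference_genus(genus_spec(n_clades = 3, n_per_clade = 2,
#'                                          seq_length = 400, seed = 7))
#' g$truth
generate_reference_genus <- function(spec) {
  stopifnot(inherits(spec, "genus_spec"))
  set.seed(spec$seed)
  anc <- strsplit(random_dna(spec$seq_length, spec$gc), "")[[1L]]
  ids <- character(0)
  seqs <- character(0)
  clade <- character(0)
  labels <- clade_labels(spec$n_clades)
  for (k in seq_len(spec$n_clades)) {
    d_root <- stats::runif(1, spec$between_root_divergence[1L],
                           spec$between_root_divergence[2L])
    root <- .mutate(anc, .position_rates(d_root, spec))
    for (m in seq_len(spec$n_per_clade)) {
      mem <- .mutate(root, .position_rates(spec$within_divergence / 2, spec))
      ids <- c(ids, sprintf("clade%s_m%02d", labels[k], m))
      seqs <- c(seqs, paste(mem, collapse = ""))
      clade <- c(clade, labels[k])
    }
  }
  structure(list(
    sequences = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    ancestor = paste(anc, collapse = ""),
    truth = data.frame(id = ids, clade = clade, stringsAsFactors = FALSE),
    spec = spec
  ), class = "genus_sim")
}

#' @export
print.genus_sim <- function(x, ...) {
  cat("genus_sim:", length(x$sequences), "sequences in",
      length(unique(x$truth$clade)), "clades of length",
      x$spec$seq_length, "nt\n")
  invisible(x)
}

#' Generate two-parent chimeras with known breakpoints
#'
#' Each chimera is the prefix of one parent up to a uniform breakpoint,
#' joined to the suffix of a parent from a *different* clade - the
#' construction that makes chimeras hard to spot, since both halves are
#' genuine genus sequences. The breakpoint is drawn uniformly in
#' `[margin, L - margin]` and recorded in the truth table.
#'
#' Chimeras are only detectable by split-and-compare screening when the two
#' parent clades actually diverge by more than the conflict margin on each
#' side of the breakpoint; `min_half_divergence` restricts generation to
#' that regime (parent pairs and breakpoints are rejection-sampled until
#' both the prefix and the suffix of the two parents differ by at least
#' this percent). Leave it `NULL` to sample parents freely.
#'
#' @param genus a `genus_sim` from [generate_reference_genus()]
#' @param n number of chimeras
#' @param margin minimum distance of the breakpoint from either end (nt)
#' @param seed integer seed
#' @param min_half_divergence optional percent divergence both parent halves
#'   must reach for a chimera to be emitted
#' @param members optional subset of member ids to draw parents from
#' @return list with `sequences` (named `DNAStringSet`) and `truth`
#'   (data.frame id, parent_a, parent_b, clade_a, clade_b, breakpoint)
#' @export
generate_chimeras <- function(genus, n = 10L, margin = 150L, seed = 1L,
                              min_half_divergence = NULL, members = NULL) {
  stopifnot(inherits(genus, "genus_sim"), n >= 1L)
  L <- genus$spec$seq_length
  if (margin >= L / 2) stop("margin must be < half the sequence length", call. = FALSE)
  tr <- genus$truth
  if (!is.null(members)) tr <- tr[tr$id %in% members, , drop = FALSE]
  clades <- unique(tr$clade)
  if (length(clades) < 2L) {
    stop("chimera generation needs references from at least 2 clades",
         call. = FALSE)
  }
  set.seed(seed)
  ss <- as.character(genus$sequences)
  half_div <- function(a, b, from, to) {
    ca <- strsplit(substr(a, from, to), "")[[1L]]
    cb <- strsplit(substr(b, from, to), "")[[1L]]
    100 * mean(ca != cb)
  }
  out <- character(n); ids <- character(n)
  truth <- data.frame(id = character(n), parent_a = character(n),
                      parent_b = character(n), clade_a = character(n),
                      clade_b = character(n), breakpoint = integer(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (attempt in seq_len(500L)) {
      pair <- sample(clades, 2L)
      pa <- sample(tr$id[tr$clade == pair[1L]], 1L)
      pb <- sample(tr$id[tr$clade == pair[2L]], 1L)
      b <- .draw_int(margin, L - margin)
      if (is.null(min_half_divergence)) break
      ok <- half_div(ss[[pa]], ss[[pb]], 1L, b) >= min_half_divergence &&
        half_div(ss[[pa]], ss[[pb]], b + 1L, L) >= min_half_divergence
      if (ok) break
      if (attempt == 500L) {
        stop("could not find parent pairs with half divergence >= ",
             min_half_divergence, "%", call. = FALSE)
      }
    }
    ids[i] <- sprintf("chimera%03d", i)
    out[i] <- paste0(substr(ss[[pa]], 1L, b), substr(ss[[pb]], b + 1L, L))
    truth[i, ] <- list(ids[i], pa, pb, pair[1L], pair[2L], b)
  }
  list(sequences = Biostrings::DNAStringSet(stats::setNames(out, ids)),
       truth = truth)
}

#' Specification of environment-labelled amplicon samples
#'
#' Emulates the structure of a public short-read screen: samples grouped in
#' environment/host categories, per-clade presence drawn by occupancy
#' probability, present clades contributing reads at a log-uniform relative
#' abundance, reads sliced from a hypervariable region of a random clade
#' member with per-base sequencing error, plus non-genus background reads
#' (random sequence at 55% GC, guaranteed to fail the 95% genus screen).
#'
#' `total_reads` per sample is the nominal sequencing depth recorded in the
#' sample table and used as the relative-abundance denominator; genus reads
#' are drawn binomially against it, while physically emitted background
#' reads are capped at `background_per_sample` (the rest of the depth is
#' implied, not materialized).
#'
#' @param samples_per_category named integer vector of sample counts per
#'   category (names from [sample_categories()])
#' @param occupancy per-clade, per-category presence probability: a scalar,
#'   a per-clade vector, or a clade x category matrix
#' @param abundance_bounds length-2 log-uniform bounds for the per-clade
#'   relative abundance fraction in positive samples
#' @param total_reads_range length-2 integer range of nominal sample depth
#' @param background_per_sample physically emitted background reads
#' @param region_mix named weights over region windows for read origin
#' @param error_rate per-base substitution error probability
#' @param read_length_range length-2 target amplicon length range (nt);
#'   clipped per region so that at least 80% of each read lies inside its
#'   source window
#' @param windows region window table, see [region_windows()]
#' @return object of class `sample_spec`
#' @export
sample_spec <- function(samples_per_category = c(
                          Freshwater = 40L, Seawater = 20L, Soil = 10L,
                          `Artificial/Anthropogenic` = 10L,
                          AquaticAnimals = 10L, Plants = 5L,
                          TerrestrialAnimals = 5L),
                        occupancy = default_occupancy(),
                        abundance_bounds = c(1e-4, 6e-4),
                        total_reads_range = c(5000L, 20000L),
                        background_per_sample = 20L,
                        region_mix = c(V1V2 = 1, V4V6 = 1, V7V8 = 1) / 3,
                        error_rate = 0.002,
                        read_length_range = c(310L, 460L),
                        windows = region_windows()) {
  bad <- setdiff(names(samples_per_category), sample_categories())
  if (length(bad) > 0L) stop("unknown category: ", bad[1L], call. = FALSE)
  if (any(abundance_bounds <= 0) || any(abundance_bounds >= 1)) {
    stop("abundance bounds must be in (0, 1)", call. = FALSE)
  }
  if (read_length_range[1L] < 50L) stop("read lengths must be >= 50", call. = FALSE)
  if (is.matrix(occupancy) && (any(occupancy < 0) || any(occupancy > 1))) {
    stop("occupancy probabilities must be in [0, 1]", call. = FALSE)
  }
  structure(list(samples_per_category = samples_per_category,
                 occupancy = occupancy,
                 abundance_bounds = abundance_bounds,
                 total_reads_range = as.integer(total_reads_range),
                 background_per_sample = as.integer(background_per_sample),
                 region_mix = region_mix,
                 error_rate = error_rate,
                 read_length_range = as.integer(read_length_range),
                 windows = validate_windows(windows)),
            class = "sample_spec")
}

#' @rdname sample_spec
#' @export
default_occupancy <- function() {
  cats <- c("Freshwater", "Seawater", "Soil", "Artificial/Anthropogenic",
            "AquaticAnimals", "Plants", "TerrestrialAnimals")
  m <- rbind(
    A = c(0.22, 0.03, 0.03, 0.03, 0.04, 0.02, 0.008),
    B = c(0.008, 0.07, 0.02, 0.02, 0.02, 0.02, 0.005),
    C = c(0.22, 0.03, 0.03, 0.03, 0.04, 0.02, 0.008),
    D = c(0.21, 0.03, 0.03, 0.03, 0.04, 0.02, 0.008),
    E = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  )
  colnames(m) <- cats
  m
}

# expand scalar / vector / matrix occupancy to a clade x category matrix
.occupancy_matrix <- function(occupancy, clades, cats) {
  if (is.matrix(occupancy)) {
    rows <- if (!is.null(rownames(occupancy))) {
      if (!all(clades %in% rownames(occupancy))) {
        stop("occupancy matrix lacks rows for clades: ",
             paste(setdiff(clades, rownames(occupancy)), collapse = ", "),
             call. = FALSE)
      }
      occupancy[clades, , drop = FALSE]
    } else occupancy
    cols <- if (!is.null(colnames(rows))) {
      miss <- setdiff(cats, colnames(rows))
      if (length(miss) > 0L) {
        stop("occupancy matrix lacks columns for categories: ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      rows[, cats, drop = FALSE]
    } else rows
    return(cols)
  }
  if (length(occupancy) == 1L) {
    return(matrix(occupancy, length(clades), length(cats),
                  dimnames = list(clades, cats)))
  }
  stopifnot(length(occupancy) == length(clades))
  matrix(rep(occupancy, length(cats)), length(clades), length(cats),
         dimnames = list(clades, cats))
}

# uniform integer draw on [a, b], safe against sample()'s scalar expansion
.draw_int <- function(a, b) {
  if (a >= b) return(a)
  sample(seq.int(a, b), 1L)
}

# choose a read span covering >= 80% window overlap
.read_span <- function(win, L, len_range) {
  wlen <- win[2L] - win[1L] + 1L
  max_len <- min(len_range[2L], floor(wlen / 0.8))
  min_len <- min(len_range[1L], max_len)
  lr <- .draw_int(min_len, max_len)
  if (lr <= wlen) {   # sub-window read
    s <- win[1L] + sample.int(wlen - lr + 1L, 1L) - 1L
    return(c(s, s + lr - 1L))
  }
  extra <- lr - wlen
  right <- min(extra %/% 2L, L - win[2L])
  left <- min(extra - right, win[1L] - 1L)
  right <- min(extra - left, L - win[2L])
  c(win[1L] - left, win[2L] + right)
}

#' Generate environment-labelled amplicon samples with ground truth
#'
#' @param genus a `genus_sim` from [generate_reference_genus()]
#' @param spec a [sample_spec()]
#' @param seed integer seed
#' @return list with `reads` (named `DNAStringSet`, `sample_id` in mcols),
#'   `samples` (data.frame sample_id, category, total_reads), and `truth`
#'   (list of data.frames: `presence` per sample x clade with true fraction
#'   and emitted read count; `reads` mapping every read to its origin)
#' @export
generate_sample_reads <- function(genus, spec = sample_spec(), seed = 1L) {
  stopifnot(inherits(genus, "genus_sim"), inherits(spec, "sample_spec"))
  L <- genus$spec$seq_length
  if (any(spec$windows$end > L)) {
    stop("region window outside reference length ", L, call. = FALSE)
  }
  set.seed(seed)
  clades <- unique(genus$truth$clade)
  cats <- names(spec$samples_per_category)
  occ <- .occupancy_matrix(spec$occupancy, clades, cats)
  ss <- as.character(genus$sequences)
  win_list <- lapply(seq_len(nrow(spec$windows)), function(i) {
    c(spec$windows$start[i], spec$windows$end[i])
  })
  names(win_list) <- spec$windows$name
  mix <- spec$region_mix[names(win_list)]
  mix <- mix / sum(mix)

  samples <- list(); presence <- list(); read_truth <- list()
  read_ids <- character(0); read_seqs <- character(0); read_sample <- character(0)
  n_read <- 0L
  for (cat in cats) {
    catslug <- gsub("[^A-Za-z]", "", cat)
    for (si in seq_len(spec$samples_per_category[[cat]])) {
      sid <- sprintf("%s_s%03d", catslug, si)
      total <- .draw_int(spec$total_reads_range[1L], spec$total_reads_range[2L])
      genus_reads <- 0L
      for (k in clades) {
        present <- stats::runif(1) < occ[k, cat]
        frac <- 0; nr <- 0L
        if (present) {
          frac <- exp(stats::runif(1, log(spec$abundance_bounds[1L]),
                                   log(spec$abundance_bounds[2L])))
          nr <- stats::rbinom(1L, total, frac)
          members <- genus$truth$id[genus$truth$clade == k]
          for (r in seq_len(nr)) {
            region <- sample(names(win_list), 1L, prob = mix)
            span <- .read_span(win_list[[region]], L, spec$read_length_range)
            member <- if (length(members) == 1L) members else sample(members, 1L)
            chars <- strsplit(substr(ss[[member]], span[1L], span[2L]), "")[[1L]]
            chars <- .mutate(chars, spec$error_rate)
            n_read <- n_read + 1L
            rid <- sprintf("%s_r%05d", sid, n_read)
            read_ids <- c(read_ids, rid)
            read_seqs <- c(read_seqs, paste(chars, collapse = ""))
            read_sample <- c(read_sample, sid)
            read_truth[[length(read_truth) + 1L]] <- data.frame(
              read_id = rid, sample_id = sid, origin = k, region = region,
              ref_start = span[1L], ref_end = span[2L],
              source_member = member, stringsAsFactors = FALSE)
          }
          genus_reads <- genus_reads + nr
        }
        presence[[length(presence) + 1L]] <- data.frame(
          sample_id = sid, category = cat, clade = k,
          present = present, fraction = frac, n_reads = nr,
          stringsAsFactors = FALSE)
      }
      n_bg <- min(spec$background_per_sample, total - genus_reads)
      for (r in seq_len(max(0L, n_bg))) {
        region <- sample(names(win_list), 1L, prob = mix)
        span <- .read_span(win_list[[region]], L, spec$read_length_range)
        n_read <- n_read + 1L
        rid <- sprintf("%s_r%05d", sid, n_read)
        read_ids <- c(read_ids, rid)
        read_seqs <- c(read_seqs, random_dna(span[2L] - span[1L] + 1L, gc = 0.55))
        read_sample <- c(read_sample, sid)
        read_truth[[length(read_truth) + 1L]] <- data.frame(
          read_id = rid, sample_id = sid, origin = "background",
          region = region, ref_start = NA_integer_, ref_end = NA_integer_,
          source_member = NA_character_, stringsAsFactors = FALSE)
      }
      samples[[length(samples) + 1L]] <- data.frame(
        sample_id = sid, category = cat, total_reads = total,
        stringsAsFactors = FALSE)
    }
  }
  reads <- Biostrings::DNAStringSet(stats::setNames(read_seqs, read_ids))
  S4Vectors::mcols(reads) <- S4Vectors::DataFrame(sample_id = read_sample,
                                                  row.names = read_ids)
  list(reads = reads,
       samples = do.call(rbind, samples),
       truth = list(presence = do.call(rbind, presence),
                    reads = if (length(read_truth)) do.call(rbind, read_truth)
                            else NULL))
}
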