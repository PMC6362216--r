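#' End-to-end amplicon survey workflow
#'
#' Chains the analysis stages on in-memory objects: species-level clade
#' delimitation of the references, the genus screen of the reads, region
#' classification of retained reads, per-region greedy OTU clustering with
#' environment attribution, ecology indices per clade and category, and a
#' neighbor-joining tree per region (OTU centroids plus the references
#' projected into the region window).
#'
#' @param refs named `DNAStringSet` of full-length reference sequences
#' @param reads named `DNAStringSet` of amplicon reads with `sample_id` in
#'   `S4Vectors::mcols()` (as produced by [generate_sample_reads()] or
#'   [read_fasta()] with `[sample=...]` headers)
#' @param samples sample table (sample_id, category, total_reads)
#' @param reference full-length sequence defining the region coordinate
#'   system (defaults to the first reference)
#' @param config a [run_config()]
#' @return list with elements `clades` (clade_partition), `screen`
#'   (read_screen), `regions` (data.frame read_id, region, ref_start,
#'   ref_end), `otus` (per-region list with `otu_set` and environment
#'   table), `ecology` (data.frame), `trees` (named list of `phylo`)
#' @export
run_workflow <- function(refs, reads, samples, reference = NULL,
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  samples <- validate_sample_table(samples)
  if (is.null(reference)) reference <- as.character(refs)[[1L]]

  partition <- delimit_clades(identity_matrix(refs),
                              threshold = config$species_identity_threshold)
  clade_map <- partition$membership

  screen <- screen_reads(reads, refs,
                         min_identity = config$screen_min_identity,
                         min_length = config$screen_min_length)
  kept <- screen$report[screen$report$retained, , drop = FALSE]

  sample_of <- S4Vectors::mcols(reads)$sample_id
  names(sample_of) <- names(reads)
  cat_of_sample <- stats::setNames(samples$category, samples$sample_id)

  regions <- data.frame(read_id = character(0), region = character(0),
                        ref_start = integer(0), ref_end = integer(0),
                        stringsAsFactors = FALSE)
  otus <- list()
  trees <- list()
  if (nrow(kept) > 0L) {
    kept_seqs <- as_seq_chars(screen$retained)
    anch <- lapply(kept$read_id, function(rid) {
      anchor(kept_seqs[[rid]], reference, id = rid)
    })
    names(anch) <- kept$read_id
    regions <- data.frame(
      read_id = kept$read_id,
      region = vapply(anch, classify_region, "",
                      windows = config$region_windows),
      ref_start = vapply(anch, function(a) a$ref_start, integer(1)),
      ref_end = vapply(anch, function(a) a$ref_end, integer(1)),
      stringsAsFactors = FALSE)

    read_cats <- cat_of_sample[sample_of[kept$read_id]]
    names(read_cats) <- kept$read_id
    for (rg in config$region_windows$name) {
      rids <- regions$read_id[regions$region == rg]
      if (length(rids) == 0L) next
      oset <- cluster_otus(screen$retained[rids],
                           threshold = config$otu_identity_threshold)
      env <- otu_environment_table(oset, read_cats,
                                   majority_fraction = config$majority_fraction)
      otus[[rg]] <- list(otu_set = oset, environment = env)

      win <- config$region_windows[config$region_windows$name == rg, ]
      ref_slices <- vapply(names(refs), function(id) {
        a <- anchor(as.character(refs)[[id]], reference, id = id)
        tryCatch(slice_region(a, win), error = function(e) "")
      }, "")
      ref_slices <- ref_slices[nchar(ref_slices) > 0L]
      tree_seqs <- c(stats::setNames(
        vapply(oset$otus, function(o) o$centroid_seq, ""),
        vapply(oset$otus, function(o) o$otu_id, "")), ref_slices)
      if (length(tree_seqs) >= 2L) {
        trees[[rg]] <- nj_tree(identity_to_distance(
          identity_matrix(Biostrings::DNAStringSet(tree_seqs), digits = NA)))
      }
    }
  }

  assignments <- if (nrow(kept) > 0L) {
    data.frame(read_id = kept$read_id,
               sample_id = unname(sample_of[kept$read_id]),
               clade = unname(clade_map[kept$best_ref]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = character(0), sample_id = character(0),
               clade = character(0), stringsAsFactors = FALSE)
  }
  ecology <- if (nrow(assignments) > 0L) {
    ecology_stats(samples, assignments)
  } else NULL

  list(clades = partition, screen = screen, regions = regions,
       otus = otus, ecology = ecology, trees = trees,
       assignments = assignments)
}
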