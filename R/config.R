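#' Run configuration
#'
#' Bundles every threshold the pipeline uses, with the defaults the analysis
#' is defined by: a 98.7% species-level identity threshold (upper bound of
#' the 98.65-98.7% range conventionally used to discriminate bacterial
#' species on 16S identity), 99% OTU clustering identity, the genus screen
#' (reads longer than 300 bp with at least 95% identity to a query), and the
#' majority fraction (0.5) for OTU environment attribution.
#'
#' @param species_identity_threshold percent identity above which two
#'   references belong to the same species-level clade (single linkage)
#' @param otu_identity_threshold percent identity for greedy OTU clustering
#' @param screen_min_identity minimum percent identity to any query for a
#'   read to be retained by the genus screen
#' @param screen_min_length reads must be strictly longer than this (nt)
#' @param majority_fraction fraction of members a single environment must
#'   exceed for an OTU to be attributed to it
#' @param random_seed integer seed used by stochastic stages
#' @param region_windows hypervariable-region windows, see [region_windows()]
#' @param chimera chimera-scan parameters, see [chimera_params()]
#' @return object of class `run_config`
#' @export
run_config <- function(species_identity_threshold = 98.7,
                       otu_identity_threshold = 99.0,
                       screen_min_identity = 95.0,
                       screen_min_length = 300L,
                       majority_fraction = 0.5,
                       random_seed = 1L,
                       region_windows = default_region_windows(),
                       chimera = chimera_params()) {
  thr <- c(species_identity_threshold, otu_identity_threshold,
           screen_min_identity)
  if (any(thr <= 0) || any(thr > 100)) {
    stop("identity thresholds must be in (0, 100]", call. = FALSE)
  }
  if (screen_min_length < 1L) stop("screen_min_length must be >= 1", call. = FALSE)
  if (majority_fraction <= 0 || majority_fraction >= 1) {
    stop("majority_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(
    species_identity_threshold = species_identity_threshold,
    otu_identity_threshold = otu_identity_threshold,
    screen_min_identity = screen_min_identity,
    screen_min_length = as.integer(screen_min_length),
    majority_fraction = majority_fraction,
    random_seed = as.integer(random_seed),
    region_windows = region_windows,
    chimera = chimera
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep their
#' defaults. `region_windows` may be given as a list of
#' `{name, start, end}` mappings.
#'
#' @param path path to a YAML file
#' @return object of class `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("species_identity_threshold", "otu_identity_threshold",
              "screen_min_identity", "screen_min_length",
              "majority_fraction", "random_seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$region_windows)) {
    args$region_windows <- do.call(rbind, lapply(y$region_windows, function(w) {
      data.frame(name = w$name, start = as.integer(w$start),
                 end = as.integer(w$end), stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(y$chimera)) {
    args$chimera <- do.call(chimera_params, y$chimera)
  }
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  cat("  species identity threshold:", x$species_identity_threshold, "%\n")
  cat("  OTU identity threshold:    ", x$otu_identity_threshold, "%\n")
  cat("  genus screen:              >", x$screen_min_length, "bp, >=",
      x$screen_min_identity, "% identity\n")
  cat("  majority fraction:         ", x$majority_fraction, "\n")
  cat("  regions:", paste(x$region_windows$name, collapse = ", "), "\n")
  invisible(x)
}
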