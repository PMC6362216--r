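#' Read 16S rRNA gene sequences from FASTA
#'
#' Sequences are stored as a named [Biostrings::DNAStringSet]. Headers are
#' parsed as `id [key=value ...]`; bracketed key=value pairs (for example
#' `[sample=s1]`) become metadata columns. Sequences are uppercased, RNA `U`
#' is converted to `T`, and any character outside the IUPAC nucleotide
#' alphabet raises a validation error naming the record and position.
#'
#' @param path path to a FASTA file
#' @return `DNAStringSet` with ids as names and parsed header fields in
#'   `S4Vectors::mcols()`
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a [sample=s1]", "acgu"), tf)
#' x <- read_fasta(tf)
#' as.character(x)          # "ACGT"
#' S4Vectors::mcols(x)$sample_id
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L || hdr_idx[1L] != 1L) {
    first_bad <- if (length(hdr_idx) == 0L) 1L else 1L
    stop("malformed FASTA at line ", first_bad,
         ": expected '>' header", call. = FALSE)
  }
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  ids <- character(length(hdr_idx))
  seqs <- character(length(hdr_idx))
  meta <- vector("list", length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    header <- sub("^>", "", lines[hdr_idx[i]])
    ids[i] <- sub("\\s.*$", "", header)
    if (!nzchar(ids[i])) {
      stop("malformed FASTA at line ", hdr_idx[i], ": empty id", call. = FALSE)
    }
    kv <- regmatches(header, gregexpr("\\[[^]=]+=[^]]*\\]", header))[[1L]]
    if (length(kv) > 0L) {
      keys <- sub("^\\[([^=]+)=.*", "\\1", kv)
      vals <- sub("^\\[[^=]+=([^]]*)\\]$", "\\1", kv)
      meta[[i]] <- stats::setNames(as.list(vals), keys)
    }
    body <- lines[seq.int(hdr_idx[i] + 1L, ends[i])]
    body <- body[!grepl("^>", body)]
    if (hdr_idx[i] == ends[i]) {
      stop("malformed FASTA at line ", hdr_idx[i], ": record '", ids[i],
           "' has no sequence", call. = FALSE)
    }
    seqs[i] <- normalize_seq(paste(gsub("\\s", "", body), collapse = ""), ids[i])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[anyDuplicated(ids)], call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  keys <- unique(unlist(lapply(meta, names)))
  if (length(keys) > 0L) {
    df <- S4Vectors::DataFrame(row.names = ids)
    for (k in keys) {
      df[[if (k == "sample") "sample_id" else k]] <-
        vapply(meta, function(m) if (!is.null(m[[k]])) m[[k]] else NA_character_, "")
    }
    S4Vectors::mcols(x) <- df
  }
  x
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()]: metadata columns are emitted as bracketed
#' `[key=value]` header fields (`sample_id` is written back as `sample`).
#'
#' @param x named `DNAStringSet` (or named character vector)
#' @param path output path
#' @param width line width for wrapping sequence text
#' @return invisibly, `path`
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- as.character(x)
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named", call. = FALSE)
  meta <- if (methods::is(x, "DNAStringSet")) S4Vectors::mcols(x) else NULL
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    header <- paste0(">", ids[i])
    if (!is.null(meta) && ncol(meta) > 0L) {
      for (k in colnames(meta)) {
        v <- meta[i, k]
        if (!is.na(v)) {
          key <- if (k == "sample_id") "sample" else k
          header <- paste0(header, " [", key, "=", v, "]")
        }
      }
    }
    writeLines(header, con)
    s <- seqs[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Closed vocabulary of sample environment categories
#'
#' The environment/host categories under which microbiome samples are
#' classified for the ecology indices. Labels outside this vocabulary must
#' be mapped by the user before import.
#'
#' @return character vector of allowed category names
#' @export
sample_categories <- function() {
  c("Freshwater", "Seawater", "Soil", "Artificial/Anthropogenic",
    "AquaticAnimals", "Plants", "TerrestrialAnimals", "Unclassified")
}

#' Read a sample metadata table
#'
#' Tab-separated file with header columns `sample_id`, `category`,
#' `total_reads`. Categories must come from [sample_categories()];
#' `total_reads` must be a positive integer; `sample_id` must be unique.
#'
#' @param path path to TSV file
#' @return data.frame with columns sample_id, category, total_reads
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "category", "total_reads")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_sample_table(df[need])
}

#' @rdname read_sample_table
#' @param df data.frame to validate in place of a file
#' @export
validate_sample_table <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[anyDuplicated(df$sample_id)],
         call. = FALSE)
  }
  bad <- setdiff(unique(df$category), sample_categories())
  if (length(bad) > 0L) {
    stop("unknown sample category '", bad[1L], "'; allowed values: ",
         paste(sample_categories(), collapse = ", "), call. = FALSE)
  }
  tr <- suppressWarnings(as.integer(df$total_reads))
  if (anyNA(tr) || any(tr < 1L)) {
    stop("total_reads must be a positive integer for every sample",
         call. = FALSE)
  }
  df$total_reads <- tr
  df
}

#' Write a tabular report as TSV
#'
#' Deterministic column order (as given), tab-separated, no quoting, no row
#' names. An empty table writes a header line only.
#'
#' @param rows data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_tsv_report <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a TSV report
#' @param path path to TSV file
#' @return data.frame
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a phylogenetic tree to newick
#'
#' Branch lengths are written with 6 decimals and the string is terminated
#' by `;`. Trees are `ape::phylo` objects.
#'
#' @param tree a `phylo` object
#' @param path optional output path; if `NULL` the newick string is returned
#' @return the newick string (invisibly when written to a file)
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt_node <- function(node, edge_idx) {
    if (node <= n_tip) {
      lab <- tree$tip.label[node]
    } else {
      kids <- children[[as.character(node)]]
      lab <- paste0("(", paste(vapply(kids, function(e) {
        fmt_node(tree$edge[e, 2L], e)
      }, ""), collapse = ","), ")")
    }
    if (!is.null(edge_idx) && !is.null(tree$edge.length)) {
      lab <- paste0(lab, ":", sprintf("%.6f", tree$edge.length[edge_idx]))
    }
    lab
  }
  nwk <- paste0(fmt_node(root, NULL), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
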