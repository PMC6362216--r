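#' IUPAC nucleotide utilities
#'
#' Expansion sets, match compatibility and expected GC weights for the 15
#' IUPAC nucleotide symbols. Two symbols are compatible (count as a match in
#' identity and probe calculations) iff their expansion sets intersect.
#'
#' @name iupac
#' @keywords internal
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

# compatibility matrix: TRUE iff expansion sets intersect; gap rows all FALSE
.build_compat <- function() {
  syms <- c(IUPAC_LETTERS, "-")
  m <- matrix(FALSE, length(syms), length(syms), dimnames = list(syms, syms))
  for (a in IUPAC_LETTERS) for (b in IUPAC_LETTERS) {
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
  }
  m
}
IUPAC_COMPAT <- .build_compat()

# expected G+C content of each symbol's expansion set
IUPAC_GC_WEIGHT <- vapply(IUPAC_SETS, function(s) {
  mean(s %in% c("G", "C"))
}, numeric(1))

# reverse lookup: sorted base set -> degenerate code
.IUPAC_CODE_LOOKUP <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(IUPAC_SETS), keys)
})

#' Collapse a set of bases to its IUPAC code
#' @param bases character vector of A/C/G/T (or degenerate) symbols
#' @return single IUPAC letter covering the union of expansions
#' @keywords internal
iupac_code <- function(bases) {
  expanded <- sort(unique(unlist(IUPAC_SETS[bases])))
  code <- .IUPAC_CODE_LOOKUP[paste(expanded, collapse = "")]
  unname(code)
}

#' Validate and normalize a nucleotide string
#'
#' Uppercases, converts U to T, and rejects any character outside the IUPAC
#' nucleotide alphabet, reporting the 1-based position of the first offender.
#'
#' @param seq character scalar
#' @param id record id used in error messages
#' @return normalized character scalar
#' @keywords internal
normalize_seq <- function(seq, id = "<seq>") {
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  if (nchar(s) == 0L) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% IUPAC_LETTERS))
  if (length(bad) > 0L) {
    stop("record '", id, "': non-IUPAC character '", chars[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  }
  s
}

#' Random DNA string with a given expected GC content
#' @param n length in nt
#' @param gc expected GC fraction
#' @return character scalar
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of an IUPAC string
#' @param seq character scalar (degenerate symbols allowed)
#' @return character scalar
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
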