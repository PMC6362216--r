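#' Pairwise global alignment with free terminal gaps
#'
#' Optimal ends-free ("overlap") global alignment under the scoring scheme
#' match +2, mismatch -1, gap -2 per position, terminal gaps free. The
#' dynamic programming is delegated to [Biostrings::pairwiseAlignment()]
#' with an IUPAC-aware substitution matrix; identity arithmetic on the
#' resulting columns is done by this package (see [percent_identity()]).
#'
#' @param a,b sequences (character scalars, `DNAString`s, or single-element
#'   `DNAStringSet`s)
#' @return list with gapped strings `pattern` and `subject` (equal length,
#'   terminal overhangs excluded), coordinates `p_start`, `p_end`,
#'   `s_start`, `s_end` of the aligned span on each input, and the alignment
#'   `score`
#' @export
global_align <- function(a, b) {
  a <- as_seq_string(a); b <- as_seq_string(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("cannot align empty sequences", call. = FALSE)
  }
  align_batch(a, b)[[1L]]
}

# vectorized ends-free alignment of several patterns against one subject;
# returns one global_align-style record per pattern
align_batch <- function(patterns, subject) {
  ps <- vapply(as.character(patterns), as_seq_string, "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(ps), Biostrings::DNAString(as_seq_string(subject)),
    type = "overlap",
    substitutionMatrix = .ALIGN_SUBST,
    gapOpening = 0, gapExtension = 2
  )
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  p_str <- as.character(pat); s_str <- as.character(sub)
  p_s <- BiocGenerics::start(pat); p_e <- BiocGenerics::end(pat)
  s_s <- BiocGenerics::start(sub); s_e <- BiocGenerics::end(sub)
  sc <- Biostrings::score(aln)
  lapply(seq_along(ps), function(i) {
    list(pattern = p_str[i], subject = s_str[i],
         p_start = p_s[i], p_end = p_e[i],
         s_start = s_s[i], s_end = s_e[i],
         score = sc[i])
  })
}

.ALIGN_SUBST <- Biostrings::nucleotideSubstitutionMatrix(
  match = 2, mismatch = -1, baseOnly = FALSE, type = "DNA"
)

# coerce a sequence set to a named character vector, preserving names
# (as.character() on a named character vector silently drops them)
as_seq_chars <- function(x) {
  nm <- names(x)
  s <- as.character(x)
  if (is.null(names(s))) names(s) <- nm
  s
}

# coerce the accepted sequence inputs to a plain character scalar
as_seq_string <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    return(toupper(x))
  }
  if (methods::is(x, "DNAString")) return(as.character(x))
  if (methods::is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(x)[[1L]])
  }
  stop("unsupported sequence type: ", class(x)[1L], call. = FALSE)
}

#' Column profile of an alignment
#'
#' Per-column match calls and query/subject coordinates for a [global_align()]
#' result. Matches follow the IUPAC intersection rule; a gap column never
#' matches. `q_fill`/`s_fill` carry the last consumed query/subject position,
#' so gap columns inherit the coordinate of the preceding column.
#'
#' @param aln result of [global_align()]
#' @return list with logical `match`, integer `q_pos`, `s_pos` (NA at gap
#'   columns), `q_fill`, `s_fill`, and `n_col`
#' @keywords internal
alignment_profile <- function(aln) {
  pc <- strsplit(aln$pattern, "", fixed = TRUE)[[1L]]
  sc <- strsplit(aln$subject, "", fixed = TRUE)[[1L]]
  n <- length(pc)
  match <- IUPAC_COMPAT[cbind(pc, sc)]
  q_pos <- ifelse(pc == "-", NA_integer_, aln$p_start - 1L + cumsum(pc != "-"))
  s_pos <- ifelse(sc == "-", NA_integer_, aln$s_start - 1L + cumsum(sc != "-"))
  q_fill <- cummax(ifelse(is.na(q_pos), 0L, q_pos))
  s_fill <- cummax(ifelse(is.na(s_pos), 0L, s_pos))
  list(match = match, q_pos = q_pos, s_pos = s_pos,
       q_fill = q_fill, s_fill = s_fill, n_col = n)
}

#' Percent identity between two sequences
#'
#' Identity is computed on the optimal ends-free global alignment as
#' `100 * matches / aligned columns`: terminal-gap columns are excluded
#' (they are trimmed by the ends-free alignment), internal gap columns count
#' as mismatches, and IUPAC-degenerate positions count as a match iff their
#' expansion sets intersect. This definition is stated explicitly because
#' printed identity percentages depend on it.
#'
#' @inheritParams global_align
#' @param digits decimals to round the reported value to (default 1, the
#'   reporting convention; use `NA` for the unrounded value)
#' @return percent identity in `[0, 100]`, with attribute `aligned_columns`
#' @export
#' @examples
#' percent_identity("ACGTACGT", "ACGTACGT")  # 100
percent_identity <- function(a, b, digits = 1) {
  aln <- global_align(a, b)
  n <- nchar(aln$pattern)
  if (n == 0L) {
    out <- 0
    attr(out, "aligned_columns") <- 0L
    return(out)
  }
  prof <- alignment_profile(aln)
  out <- 100 * sum(prof$match) / prof$n_col
  if (!is.na(digits)) out <- round(out, digits)
  attr(out, "aligned_columns") <- prof$n_col
  out
}

#' Full pairwise identity matrix
#'
#' @param seqs named `DNAStringSet` (or named character vector) of at least
#'   two sequences
#' @param digits see [percent_identity()]
#' @return symmetric numeric matrix with 100 on the diagonal, dimnames the
#'   sequence ids
#' @export
identity_matrix <- function(seqs, digits = 1) {
  ss <- as_seq_chars(seqs)
  ids <- names(ss)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must have unique names", call. = FALSE)
  }
  n <- length(ss)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    recs <- align_batch(ss[seq.int(i + 1L, n)], ss[[i]])
    for (j in seq_along(recs)) {
      prof <- alignment_profile(recs[[j]])
      v <- if (prof$n_col == 0L) 0 else 100 * sum(prof$match) / prof$n_col
      if (!is.na(digits)) v <- round(v, digits)
      m[i, i + j] <- v
      m[i + j, i] <- v
    }
  }
  m
}
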