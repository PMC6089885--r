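# Global pairwise protein alignment for channel paralog comparison
# (identity/similarity percentages and interface residue correspondence).

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

.subst_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under affine gap penalties with end gaps
#' penalized (EMBOSS-needle conventions: gap cost = `gap_open` +
#' `gap_extend` per gap position). Identity is the percentage of identical
#' columns over the full alignment length (gap columns included in the
#' denominator); similarity additionally counts columns whose substitution
#' score is positive.
#'
#' @param seq1,seq2 protein sequences (strings over the 20-letter alphabet;
#'   `X` tolerated).
#' @param matrix substitution matrix name (default `"BLOSUM62"`) or a
#'   numeric matrix.
#' @param gap_open gap opening penalty, default 10.
#' @param gap_extend gap extension penalty, default 0.5.
#' @return object of class `scored_alignment`: `aligned_seq1`,
#'   `aligned_seq2` (gapped strings of equal length), `score`,
#'   `identity_pct`, `similarity_pct`, `n_identical`, `n_similar`,
#'   `alignment_length`.
#' @export
needleman_wunsch_align <- function(seq1, seq2, matrix = "BLOSUM62",
                                   gap_open = 10, gap_extend = 0.5) {
  for (nm in c("seq1", "seq2")) {
    s <- get(nm)
    if (!is.character(s) || length(s) != 1L || nchar(s) == 0L)
      stop(nm, " must be a single non-empty string", call. = FALSE)
    bad <- which(!strsplit(toupper(s), "")[[1]] %in% .aa_alphabet)
    if (length(bad))
      stop("illegal characters in ", nm, " at positions ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- .subst_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq1)), Biostrings::AAString(toupper(seq2)),
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  a1 <- as.character(Biostrings::alignedPattern(aln))
  a2 <- as.character(Biostrings::alignedSubject(aln))
  c1 <- strsplit(a1, "")[[1]]; c2 <- strsplit(a2, "")[[1]]
  len <- length(c1)
  nongap <- c1 != "-" & c2 != "-"
  ident <- nongap & c1 == c2
  pos <- nongap
  pos[nongap] <- sm[cbind(c1[nongap], c2[nongap])] > 0
  similar <- ident | pos
  structure(list(aligned_seq1 = a1, aligned_seq2 = a2,
                 score = Biostrings::score(aln),
                 identity_pct = 100 * sum(ident) / len,
                 similarity_pct = 100 * sum(similar) / len,
                 n_identical = sum(ident), n_similar = sum(similar),
                 alignment_length = len),
            class = "scored_alignment")
}

#' @export
print.scored_alignment <- function(x, ...) {
  cat(sprintf("global alignment: length %d, score %.1f\n", x$alignment_length,
              x$score))
  cat(sprintf("  identity %.1f%% (%d/%d), similarity %.1f%% (%d/%d)\n",
              x$identity_pct, x$n_identical, x$alignment_length,
              x$similarity_pct, x$n_similar, x$alignment_length))
  invisible(x)
}

#' Aligned columns where the two sequences differ
#'
#' Walks the alignment and reports every non-identical column (substitution
#' or gap) whose seq1 position falls in `region`. Positions are 1-based
#' sequence numbering; a gap yields `NA` for the absent side.
#'
#' @param aln scored_alignment.
#' @param region optional `c(lo, hi)` range on seq1; default the whole
#'   sequence.
#' @return data.frame with columns `column`, `pos1`, `res1`, `pos2`, `res2`.
#' @export
interface_difference_positions <- function(aln, region = NULL) {
  c1 <- strsplit(aln$aligned_seq1, "")[[1]]
  c2 <- strsplit(aln$aligned_seq2, "")[[1]]
  len1 <- sum(c1 != "-")
  if (is.null(region)) region <- c(1L, len1)
  if (region[1] < 1 || region[2] > len1 || region[1] > region[2])
    stop("region out of range: seq1 has ", len1, " residues", call. = FALSE)
  p1 <- cumsum(c1 != "-"); p2 <- cumsum(c2 != "-")
  # a gap-in-seq1 column carries the seq1 position of the preceding residue
  diffs <- which(c1 != c2 & p1 >= region[1] & p1 <= region[2])
  data.frame(column = diffs,
             pos1 = ifelse(c1[diffs] == "-", NA_integer_, p1[diffs]),
             res1 = c1[diffs],
             pos2 = ifelse(c2[diffs] == "-", NA_integer_, p2[diffs]),
             res2 = c2[diffs])
}

#' Map a seq1 position to its aligned seq2 position
#'
#' @param aln scored_alignment.
#' @param pos1 1-based position on seq1.
#' @return list with `pos2` (1-based position on seq2, `NA` if aligned to a
#'   gap), `res1`, `res2`.
#' @export
aligned_position <- function(aln, pos1) {
  c1 <- strsplit(aln$aligned_seq1, "")[[1]]
  c2 <- strsplit(aln$aligned_seq2, "")[[1]]
  p1 <- cumsum(c1 != "-"); p2 <- cumsum(c2 != "-")
  col <- which(p1 == pos1 & c1 != "-")
  if (length(col) != 1L) stop("position out of range", call. = FALSE)
  list(pos2 = if (c2[col] == "-") NA_integer_ else p2[col],
       res1 = c1[col], res2 = c2[col])
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}
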