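#' Globally align a splice isoform to its canonical protein
#'
#' Needleman-Wunsch global alignment with affine gap penalties, the setting
#' used to transfer canonical TM-domain annotations onto splice isoforms.
#' Defaults are BLOSUM62 with gap open 10 / extend 1; a custom substitution
#' matrix (e.g. a unit match/mismatch matrix) can be supplied for controlled
#' comparisons.
#'
#' @param canonical,isoform Protein sequences (standard one-letter codes;
#'   anything else is an error).
#' @param substitution_matrix Name of a matrix shipped with Biostrings
#'   (default `"BLOSUM62"`) or a numeric substitution matrix.
#' @param gap_open,gap_extend Non-negative gap penalties (a k-residue gap
#'   costs `gap_open + k * gap_extend`).
#' @return List of class `alignment_result` with `aligned_canonical` and
#'   `aligned_isoform` (equal-length gapped strings whose degapping
#'   reproduces the inputs) and `score`.
#' @export
align_isoform <- function(canonical, isoform,
                          substitution_matrix = "BLOSUM62",
                          gap_open = 10, gap_extend = 1) {
  if (!nzchar(canonical) || !nzchar(isoform))
    stop("both sequences must be non-empty")
  validate_protein(canonical)
  validate_protein(isoform)
  canonical <- toupper(canonical); isoform <- toupper(isoform)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(canonical),
    subject = Biostrings::AAString(isoform),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  ac <- as.character(Biostrings::alignedPattern(pa))
  ai <- as.character(Biostrings::alignedSubject(pa))
  stopifnot(nchar(ac) == nchar(ai),
            gsub("-", "", ac, fixed = TRUE) == canonical,
            gsub("-", "", ai, fixed = TRUE) == isoform)
  structure(list(aligned_canonical = unname(ac), aligned_isoform = unname(ai),
                 score = Biostrings::score(pa)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("alignment_result:", nchar(x$aligned_canonical), "columns, score",
      x$score, "\n")
  invisible(x)
}

#' Basic global nucleotide aligner for small demo inputs
#'
#' Match +1, mismatch -1, gap -2 (linear). Intended only to produce pairwise
#' alignments for small demonstration inputs; production alignments are
#' consumed as aligned FASTA.
#'
#' @param a,b Nucleotide sequences.
#' @return A [pairwise_alignment()] object.
#' @export
align_nucleotide <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(a)),
    subject = Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  pairwise_alignment(as.character(Biostrings::alignedPattern(pa)),
                     as.character(Biostrings::alignedSubject(pa)))
}
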