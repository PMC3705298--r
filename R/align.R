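# Pairwise overlap alignment: affine-gap Needleman-Wunsch with free end
# gaps, scored with an EDNAFULL-style nucleotide matrix.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' IUPAC nucleotide scoring matrix
#'
#' EDNAFULL-style matrix: identical unambiguous bases score `match`,
#' different bases score `mismatch`, and pairs involving ambiguity codes
#' score the mean over all base pairs in the two codes' sets (so e.g.
#' A vs R scores `(match + mismatch) / 2`).
#'
#' @param match Score for identical bases (default 5).
#' @param mismatch Score for differing bases (default -4).
#' @return A 15 x 15 numeric matrix over the IUPAC alphabet.
#' @export
iupac_score_matrix <- function(match = 5, mismatch = -4) {
  ab <- names(IUPAC_SETS)
  m <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
  for (x in ab) for (y in ab) {
    grid <- expand.grid(a = IUPAC_SETS[[x]], b = IUPAC_SETS[[y]],
                        stringsAsFactors = FALSE)
    m[x, y] <- mean(ifelse(grid$a == grid$b, match, mismatch))
  }
  m
}

#' Alignment and merge parameters
#'
#' Defaults mirror the published defaults of the EMBOSS `merger` program:
#' +5/-4 nucleotide scores, gap open 50, gap extension 0.5, end gaps free.
#' `min_overlap_score` is the score below which two fragments are deemed
#' not to overlap (one error-free 4-mer's worth of matches); see
#' [merge_pair()].
#'
#' @param match,mismatch Substitution scores (see [iupac_score_matrix()]).
#' @param gap_open Penalty for opening a gap (first gapped base).
#' @param gap_extend Penalty per additional gapped base.
#' @param min_overlap_score Minimum overlap alignment score for a merge to
#'   be considered real (default 20).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(match = 5, mismatch = -4, gap_open = 50,
                             gap_extend = 0.5, min_overlap_score = 20) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(
    list(matrix = iupac_score_matrix(match, mismatch),
         alphabet = paste(names(IUPAC_SETS), collapse = ""),
         gap_open = gap_open, gap_extend = gap_extend,
         min_overlap_score = min_overlap_score),
    class = "alignment_params"
  )
}

#' Globally align two sequences with free end gaps
#'
#' Needleman-Wunsch alignment with affine gap penalties (a gap run of
#' length k costs `gap_open + (k - 1) * gap_extend`) in which gap runs
#' touching either sequence end are free, so the optimal alignment overlaps
#' the two sequences rather than stretching them end to end. Traceback ties
#' are broken deterministically: diagonal, then gap in `b`, then gap in `a`.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param params An [alignment_params()] object.
#' @return A list with `aligned_a` and `aligned_b` (equal-length gapped
#'   strings whose gap-free characters reproduce the inputs, case kept) and
#'   `score` (the overlap-region score; end gaps contribute nothing).
#' @examples
#' align_overlap("ACGTACGTAA", "GTAACGGTT")
#' @export
align_overlap <- function(a, b, params = alignment_params()) {
  stopifnot(nchar(a) >= 1L, nchar(b) >= 1L)
  res <- cpp_align_overlap(toupper(a), toupper(b), params$matrix,
                           params$alphabet, params$gap_open, params$gap_extend)
  # restore input case into the gapped strings
  recase <- function(aligned, original) {
    al <- chars(aligned)
    al[al != "-"] <- chars(original)
    paste(al, collapse = "")
  }
  list(aligned_a = recase(res$aligned_a, a),
       aligned_b = recase(res$aligned_b, b),
       score = res$score)
}
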