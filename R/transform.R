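# Sequence orientation and circular-rotation helpers.

IUPAC_FROM <- "ACGTURYSWKMBVDHN"
IUPAC_TO   <- "TGCAAYRSWMKVBHDN"

#' Reverse a nucleotide sequence
#' @param seq Nucleotide string.
#' @return The characters of `seq` in reverse order.
#' @export
seq_reverse <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  paste(rev(chars(seq)), collapse = "")
}

#' Complement a nucleotide sequence
#'
#' IUPAC-aware per-base complement (A<->T, C<->G, R<->Y, K<->M, B<->V,
#' D<->H; S, W and N are self-complementary). Case is preserved; gap
#' characters pass through.
#'
#' @param seq Nucleotide string.
#' @return The complemented sequence (not reversed).
#' @export
seq_complement <- function(seq) {
  bad <- gsub(sprintf("[%s%s.-]", IUPAC_FROM, tolower(IUPAC_FROM)), "", seq)
  if (nchar(bad) > 0L) {
    stop("invalid base in sequence: '", substr(bad, 1, 1), "'", call. = FALSE)
  }
  chartr(paste0(IUPAC_FROM, tolower(IUPAC_FROM)),
         paste0(IUPAC_TO, tolower(IUPAC_TO)), seq)
}

#' Reverse-complement a nucleotide sequence
#' @param seq Nucleotide string.
#' @return `seq_reverse(seq_complement(seq))`.
#' @export
seq_revcomp <- function(seq) seq_reverse(seq_complement(seq))

#' Rotate a circular sequence so a motif starts at a target position
#'
#' For assemblies of circular genomes, slides (rotates) the sequence so
#' that `motif` begins at 1-based coordinate `position` — e.g. the HBV
#' convention that the EcoRI site GAATTC starts at position 1. The motif is
#' searched circularly (it may straddle the sequence end) and
#' case-insensitively; if it occurs more than once, the first circular
#' occurrence is used with a warning.
#'
#' @param seq Nucleotide string representing a circular molecule.
#' @param motif Landmark motif (exact match, no ambiguity expansion).
#' @param position 1-based coordinate at which the motif should start in
#'   the output (default 1).
#' @return A rotation of `seq` with `motif` starting at `position`.
#' @examples
#' seq_slide("TTGAATTCAA", "GAATTC", 1)
#' @export
seq_slide <- function(seq, motif, position = 1L) {
  stopifnot(nchar(motif) >= 1L, position >= 1L)
  n <- nchar(seq)
  position <- as.integer(position)
  if (position > n) stop("slide position beyond sequence length", call. = FALSE)
  m <- nchar(motif)
  circ <- toupper(paste0(seq, substr(seq, 1L, min(m - 1L, n))))
  hits <- gregexpr(toupper(motif), circ, fixed = TRUE)[[1]]
  hits <- hits[hits > 0 & hits <= n]
  if (length(hits) == 0L) stop("slide motif not found", call. = FALSE)
  if (length(hits) > 1L) {
    warning("slide motif found ", length(hits),
            " times; using first circular occurrence", call. = FALSE)
  }
  hit <- hits[1]                         # 1-based motif start in seq
  shift <- (hit - position) %% n         # left-rotation amount
  if (shift == 0L) return(seq)
  paste0(substr(seq, shift + 1L, n), substr(seq, 1L, shift))
}

#' Double a reference sequence for circular-assembly checking
#'
#' Concatenates a reference with itself so that any rotation of a circular
#' assembly aligns to it without wrap-around end gaps; the end of the first
#' copy sits adjacent to the start of the second.
#'
#' @param ref A list or one-row data frame with `id` and `sequence`.
#' @return A list with `id` (suffixed `"_x2"`) and the doubled `sequence`.
#' @export
double_reference <- function(ref) {
  ref <- as_seq_record(ref, default_id = "reference")
  stopifnot(nchar(ref$sequence) >= 1L)
  list(id = paste0(ref$id, "_x2"),
       sequence = paste0(ref$sequence, ref$sequence))
}
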