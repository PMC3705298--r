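# Post-merge validation against reference sequences.
#
# References are never used to build the merged sequence; they are aligned
# to it afterwards as a quick visual/numeric check. For several references
# the merged sequence seeds a progressive alignment: each reference is
# aligned to it pairwise and the pairwise alignments are reconciled into
# one multiple alignment by inserting gap columns.

#' Check a merged sequence against reference sequences
#'
#' @param merged The merged sequence: character string, `list(id,
#'   sequence)` or one-row data frame.
#' @param refs A data frame with columns `id` and `sequence` (one row per
#'   reference), e.g. from [read_fasta()].
#' @param params An [alignment_params()] object.
#' @return An object of class `ref_check`: list with `rows` (named
#'   character vector of equal-length gapped rows, merged first),
#'   `match_line` (`"|"` where every row carries the identical base, `" "`
#'   otherwise; gaps count as disagreement), `n_matches`, `n_mismatches`.
#' @examples
#' check_against_references("ACGTACGT", tibble::tibble(id = "r", sequence = "ACGTACGT"))
#' @export
check_against_references <- function(merged, refs,
                                     params = alignment_params()) {
  merged <- as_seq_record(merged, "merged")
  if (is.null(refs) || nrow(refs) == 0L) {
    stop("no references given", call. = FALSE)
  }
  L <- nchar(merged$sequence)

  # Per reference: which merged base each ref char aligns to, plus any ref
  # characters inserted between merged bases (slot p = after merged base p).
  views <- lapply(seq_len(nrow(refs)), function(t) {
    al <- align_overlap(merged$sequence, refs$sequence[[t]], params)
    ca <- chars(al$aligned_a); cb <- chars(al$aligned_b)
    slot <- cumsum(ca != "-")             # 0..L, per column
    at_base <- rep("-", L)
    at_base[slot[ca != "-"]] <- cb[ca != "-"]
    ins <- vapply(0:L, function(p) {
      paste(cb[slot == p & ca == "-"], collapse = "")
    }, character(1))
    list(at_base = at_base, ins = ins)
  })

  ins_width <- do.call(pmax, lapply(views, function(v) nchar(v$ins)))
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))

  merged_chars <- chars(merged$sequence)
  build_row <- function(ins, at_base) {
    pieces <- character(2L * L + 1L)
    pieces[1L] <- pad(ins[1L], ins_width[1L])
    pieces[2L * (1:L)] <- at_base
    pieces[2L * (1:L) + 1L] <- pad(ins[1:L + 1L], ins_width[1:L + 1L])
    paste(pieces, collapse = "")
  }
  rows <- c(
    stats::setNames(build_row(rep("", L + 1L), merged_chars), merged$id),
    stats::setNames(
      vapply(views, function(v) build_row(v$ins, v$at_base), character(1)),
      refs$id)
  )

  mat <- do.call(rbind, lapply(rows, function(r) toupper(chars(r))))
  agree <- apply(mat, 2L, function(col) all(col == col[1L]) && col[1L] != "-")
  match_line <- paste(ifelse(agree, "|", " "), collapse = "")

  structure(
    list(rows = rows, match_line = match_line,
         n_matches = sum(agree), n_mismatches = sum(!agree)),
    class = "ref_check"
  )
}

#' @export
print.ref_check <- function(x, width = 60L, ...) {
  cat(sprintf("<ref_check> %d sequences, %d matches / %d mismatches over %d columns\n",
              length(x$rows), x$n_matches, x$n_mismatches,
              nchar(x$match_line)))
  invisible(x)
}

# Interleaved plain-text rendering (rows + match line in blocks).
format_ref_check <- function(x, width = 60L) {
  len <- nchar(x$match_line)
  namew <- max(nchar(names(x$rows))) + 2L
  out <- character(0)
  for (start in seq(1L, len, by = width)) {
    end <- min(start + width - 1L, len)
    for (nm in names(x$rows)) {
      out <- c(out, sprintf("%-*s%s", namew, nm,
                            substr(x$rows[[nm]], start, end)))
    }
    out <- c(out, sprintf("%-*s%s", namew, "",
                          substr(x$match_line, start, end)), "")
  }
  c(out, sprintf("matches: %d  mismatches: %d", x$n_matches, x$n_mismatches))
}
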