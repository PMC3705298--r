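# FASTA reading/writing and the tool's FASTA-ID bookkeeping.
#
# IDs are the full header line after ">" (spaces kept) because trim
# annotations are appended to them in human-readable form. Case is
# preserved on read; alignment upper-cases internally.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (one or more records).
#' @return A tibble with columns `id` (full header without `>`) and
#'   `sequence` (case preserved, line wraps joined).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  first <- head_lines[nzchar(trimws(head_lines))][1]
  if (is.na(first) || !startsWith(trimws(first), ">")) {
    stop("not FASTA: ", path, call. = FALSE)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not FASTA: ", path, call. = FALSE))
  if (length(set) == 0L) stop("not FASTA: ", path, call. = FALSE)
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty sequence record in ", path, call. = FALSE)
  }
  tibble::tibble(id = names(set), sequence = unname(as.character(set)))
}

#' Write records to a FASTA file
#'
#' @param records A data frame with columns `id` and `sequence`, or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- tibble::tibble(id = names(records) %||% paste0("seq", seq_along(records)),
                              sequence = unname(records))
  }
  stopifnot(nrow(records) >= 1L, width >= 1L)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Append trim parameters to a FASTA ID
#'
#' Trimmed chromatogram sequences carry their trim window and threshold in
#' the FASTA ID for later reference. The annotation is applied at most once.
#'
#' @param id FASTA ID.
#' @param window,threshold Trim parameters used.
#' @return Annotated ID, e.g. `"frag1 trimmed(w=10,t=20)"`.
#' @export
annotate_trimmed_id <- function(id, window, threshold) {
  if (is_trim_annotated(id)) return(id)
  sprintf("%s trimmed(w=%d,t=%d)", id, as.integer(window), as.integer(threshold))
}

is_trim_annotated <- function(id) {
  grepl(" trimmed\\(w=[0-9]+,t=[0-9]+\\)", id)
}

#' Choose the merged sequence's FASTA ID
#'
#' The user-supplied ID wins; when it is missing or blank, the ID of the
#' first fragment submitted is used.
#'
#' @param user_id Optional user-supplied ID (may be `NULL`, `NA` or blank).
#' @param first_fragment_id ID of the first fragment in merge order.
#' @return The ID to use for the final merged sequence.
#' @export
merged_sequence_id <- function(user_id, first_fragment_id) {
  stopifnot(nzchar(first_fragment_id))
  if (is.null(user_id) || length(user_id) == 0L || is.na(user_id) ||
      !nzchar(trimws(user_id))) {
    return(first_fragment_id)
  }
  user_id
}
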