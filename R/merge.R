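# Pairwise overlap merging and sequential chain merging.

#' Merge two overlapping sequences
#'
#' Aligns `a` and `b` globally with free end gaps ([align_overlap()]) and
#' reads the merged sequence off the alignment column by column: columns
#' where only one sequence has a base contribute that base; agreeing
#' columns contribute the shared base; disagreeing columns are recorded as
#' conflicts and resolved by quality (higher Phred score wins when both
#' fragments carry scores), falling back to position (the base farther from
#' its own fragment's nearer end wins, trusting read middles over read
#' ends), and finally to fragment `a`.
#'
#' Orientation is `"CORRECT"` when the overlap joins the 3' end of `a` to
#' the 5' end of `b` — the expectation for fragments supplied in merge
#' order — and `"CHECK"` otherwise. When the best overlap scores below
#' `params$min_overlap_score` the sequences are deemed non-overlapping and
#' are concatenated sharing exactly one nucleotide, with orientation
#' `"CHECK"`.
#'
#' @param a,b Sequences to merge: character strings, `list(id, sequence)`,
#'   or one-row data frames. `a` is the left (earlier) fragment.
#' @param qual_a,qual_b Optional per-base quality vectors for `a` and `b`.
#' @param params An [alignment_params()] object.
#' @return An object of class `merge_report`: list with `merged` (list of
#'   `id`, `sequence`), `score`, `overlap_len` (columns where both
#'   sequences have a base), `conflicts` (tibble: `merged_position`,
#'   `base_a`, `base_b`, `chosen`, `rule`), `orientation`, `aligned_a`,
#'   `aligned_b`.
#' @examples
#' merge_pair("ACGTACGTAA", "GTAACGGTT")
#' @export
merge_pair <- function(a, b, qual_a = NULL, qual_b = NULL,
                       params = alignment_params()) {
  a <- as_seq_record(a, "a"); b <- as_seq_record(b, "b")
  if (nchar(a$sequence) == 0L || nchar(b$sequence) == 0L) {
    stop("empty fragment", call. = FALSE)
  }
  al <- align_overlap(a$sequence, b$sequence, params)
  if (al$score < params$min_overlap_score) {
    return(concat_fallback(a, b, qual_a, qual_b, params))
  }

  ca <- chars(al$aligned_a); cb <- chars(al$aligned_b)
  gap_a <- ca == "-"; gap_b <- cb == "-"
  ai <- cumsum(!gap_a); bi <- cumsum(!gap_b)   # per-column base index
  both <- !gap_a & !gap_b
  overlap_len <- sum(both)

  chosen <- ifelse(gap_a, cb, ca)
  mism <- both & toupper(ca) != toupper(cb)
  conflicts <- resolve_conflicts(which(mism), ca, cb, ai, bi,
                                 nchar(a$sequence), nchar(b$sequence),
                                 qual_a, qual_b)
  chosen[conflicts$merged_position] <- conflicts$chosen

  lead_gap_a <- match(FALSE, gap_a) - 1L                 # b overhang at 5'
  trail_gap_b <- length(gap_b) - max(which(!gap_b))      # a overhang at 3'
  orientation <- if (lead_gap_a == 0L && trail_gap_b == 0L) "CORRECT" else "CHECK"

  new_merge_report(
    merged = list(id = a$id, sequence = paste(chosen, collapse = "")),
    score = al$score, overlap_len = overlap_len, conflicts = conflicts,
    orientation = orientation, aligned_a = al$aligned_a,
    aligned_b = al$aligned_b
  )
}

# Conflict resolution for mismatching overlap columns.
resolve_conflicts <- function(cols, ca, cb, ai, bi, len_a, len_b,
                              qual_a, qual_b) {
  n <- length(cols)
  chosen <- character(n); rule <- character(n)
  for (k in seq_len(n)) {
    col <- cols[k]
    pa <- ai[col]; pb <- bi[col]
    qa <- if (!is.null(qual_a)) qual_a[pa] else NA_integer_
    qb <- if (!is.null(qual_b)) qual_b[pb] else NA_integer_
    if (!is.na(qa) && !is.na(qb) && qa != qb) {
      chosen[k] <- if (qa > qb) ca[col] else cb[col]
      rule[k] <- "quality"
    } else {
      da <- min(pa - 1L, len_a - pa)   # distance to a's nearer end
      db <- min(pb - 1L, len_b - pb)
      if (db > da) {
        chosen[k] <- cb[col]; rule[k] <- "position"
      } else if (da > db) {
        chosen[k] <- ca[col]; rule[k] <- "position"
      } else {
        chosen[k] <- ca[col]; rule[k] <- "tie->a"
      }
    }
  }
  tibble::tibble(merged_position = cols,
                 base_a = ca[cols], base_b = cb[cols],
                 chosen = chosen, rule = rule)
}

# Degenerate merge: no credible overlap, concatenate with one shared base.
concat_fallback <- function(a, b, qual_a, qual_b, params) {
  la <- nchar(a$sequence); lb <- nchar(b$sequence)
  last_a <- substr(a$sequence, la, la)
  first_b <- substr(b$sequence, 1L, 1L)
  gaps <- function(k) strrep("-", k)
  aligned_a <- paste0(a$sequence, gaps(lb - 1L))
  aligned_b <- paste0(gaps(la - 1L), b$sequence)
  conflicts <- if (toupper(last_a) != toupper(first_b)) {
    resolve_conflicts(la, chars(aligned_a), chars(aligned_b),
                      c(seq_len(la), rep(la, lb - 1L)),
                      c(rep(1L, la - 1L), seq_len(lb)),
                      la, lb, qual_a, qual_b)
  } else {
    tibble::tibble(merged_position = integer(), base_a = character(),
                   base_b = character(), chosen = character(),
                   rule = character())
  }
  kept_first <- if (nrow(conflicts) == 1L) conflicts$chosen else last_a
  merged <- paste0(substr(a$sequence, 1L, la - 1L), kept_first,
                   substr(b$sequence, 2L, lb))
  mat <- params$matrix
  score <- mat[toupper(last_a), toupper(first_b)]
  new_merge_report(
    merged = list(id = a$id, sequence = merged),
    score = score, overlap_len = 1L, conflicts = conflicts,
    orientation = "CHECK", aligned_a = aligned_a, aligned_b = aligned_b
  )
}

new_merge_report <- function(merged, score, overlap_len, conflicts,
                             orientation, aligned_a, aligned_b) {
  structure(
    list(merged = merged, score = score, overlap_len = overlap_len,
         conflicts = conflicts, orientation = orientation,
         aligned_a = aligned_a, aligned_b = aligned_b),
    class = "merge_report"
  )
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(
    "<merge_report> %d nt merged (score %.1f, overlap %d nt, %d conflict%s, orientation %s)\n",
    nchar(x$merged$sequence), x$score, x$overlap_len, nrow(x$conflicts),
    if (nrow(x$conflicts) == 1L) "" else "s", x$orientation))
  invisible(x)
}

#' Merge an ordered series of fragments
#'
#' Left-fold of [merge_pair()] over 2-12 prepared fragments (already
#' trimmed and oriented), reproducing sequential pairwise merging: the
#' output of each merge is the left input of the next, so n fragments
#' yield exactly n - 1 merges. Intermediate merged sequences carry no
#' quality scores, so conflicts in later merges fall back to the positional
#' rule.
#'
#' @param fragments A data frame with columns `id` and `sequence` (rows in
#'   merge order), or a list of `list(id, sequence)` records.
#' @param qualities Optional list of per-fragment quality vectors (`NULL`
#'   entries allowed, e.g. for FASTA fragments).
#' @param params An [alignment_params()] object.
#' @param max_fragments Upper bound on the fragment count (default 12).
#' @param max_merged_length Merged lengths above this trigger a warning
#'   (default 100000).
#' @return An object of class `merge_chain`: list with `final` (list of
#'   `id`, `sequence`), `merges` (list of `merge_report`s, length n - 1)
#'   and `fragment_count`.
#' @export
merge_chain <- function(fragments, qualities = NULL,
                        params = alignment_params(), max_fragments = 12L,
                        max_merged_length = 100000L) {
  recs <- if (is.data.frame(fragments)) {
    lapply(seq_len(nrow(fragments)), function(i) as_seq_record(fragments[i, ]))
  } else {
    lapply(fragments, as_seq_record)
  }
  n <- length(recs)
  if (n < 2L) stop("need at least two fragments", call. = FALSE)
  if (n > max_fragments) {
    stop("too many fragments (", n, " > ", max_fragments, ")", call. = FALSE)
  }
  if (any(vapply(recs, function(r) nchar(r$sequence), integer(1)) == 0L)) {
    stop("empty fragment", call. = FALSE)
  }
  if (is.null(qualities)) qualities <- vector("list", n)

  current <- recs[[1]]
  qual_current <- qualities[[1]]
  merges <- vector("list", n - 1L)
  for (i in 2:n) {
    rep_i <- merge_pair(current, recs[[i]], qual_current, qualities[[i]],
                        params)
    merges[[i - 1L]] <- rep_i
    current <- rep_i$merged
    qual_current <- NULL   # qualities are not propagated through merges
  }
  if (nchar(current$sequence) > max_merged_length) {
    warning("merged sequence length ", nchar(current$sequence),
            " exceeds ", max_merged_length, " nt", call. = FALSE)
  }
  structure(list(final = current, merges = merges, fragment_count = n),
            class = "merge_chain")
}

#' @export
print.merge_chain <- function(x, ...) {
  cat(sprintf("<merge_chain> %d fragments -> %d merges -> %d nt (%s)\n",
              x$fragment_count, length(x$merges),
              nchar(x$final$sequence), x$final$id))
  invisible(x)
}
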