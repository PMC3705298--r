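# broom-style tidiers and ggplot2 autoplot methods for pipeline results.

#' @describeIn merge_chain One row per pairwise merge: `merge`, `score`,
#'   `overlap_len`, `n_conflicts`, `orientation`, `merged_length`.
#' @param x A `merge_chain` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.merge_chain <- function(x, ...) {
  tibble::tibble(
    merge = seq_along(x$merges),
    score = vapply(x$merges, function(m) m$score, numeric(1)),
    overlap_len = vapply(x$merges, function(m) m$overlap_len, numeric(1)),
    n_conflicts = vapply(x$merges, function(m) nrow(m$conflicts), integer(1)),
    orientation = vapply(x$merges, function(m) m$orientation, character(1)),
    merged_length = vapply(x$merges, function(m) nchar(m$merged$sequence),
                           integer(1))
  )
}

#' @describeIn merge_chain One-row summary: `fragment_count`, `n_merges`,
#'   `final_length`, `total_conflicts`, `all_correct`.
#' @exportS3Method generics::glance
glance.merge_chain <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    fragment_count = x$fragment_count,
    n_merges = length(x$merges),
    final_length = nchar(x$final$sequence),
    total_conflicts = sum(td$n_conflicts),
    all_correct = all(td$orientation == "CORRECT")
  )
}

#' Conflicts of a merge chain as one table
#'
#' @param x A `merge_chain` or `merge_run`.
#' @return Tibble of all conflicts with a leading `merge` column.
#' @export
merge_conflicts <- function(x) {
  if (inherits(x, "merge_run")) x <- x$chain
  stopifnot(inherits(x, "merge_chain"))
  dplyr::bind_rows(lapply(seq_along(x$merges), function(k) {
    cf <- x$merges[[k]]$conflicts
    if (nrow(cf) == 0L) return(NULL)
    dplyr::mutate(cf, merge = k, .before = 1L)
  }))
}

#' @describeIn run_merge Per-fragment summary rows (order, type, lengths,
#'   trim counts, percent retained, flag).
#' @param x A `merge_run` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.merge_run <- function(x, ...) {
  dplyr::select(x$fragments, "order", "name", "type", "original_length",
                "trimmed_length", "left_trimmed", "right_trimmed",
                "percent_retained", "flag")
}

#' @describeIn run_merge One-row run summary, including the reference
#'   check counts when a reference was supplied.
#' @exportS3Method generics::glance
glance.merge_run <- function(x, ...) {
  g <- glance(x$chain)
  g$merged_id <- x$merged$id
  g$slide_applied <- if (is.null(x$slide)) NA else x$slide$applied
  g$ref_matches <- if (is.null(x$ref_check)) NA_integer_ else x$ref_check$n_matches
  g$ref_mismatches <- if (is.null(x$ref_check)) NA_integer_ else x$ref_check$n_mismatches
  g
}

FLAG_COLOURS <- c(GREEN = "#2e7d32", YELLOW = "#f9a825", RED = "#c62828",
                  BLUE = "#1565c0")

#' Plot per-fragment trimming outcome
#'
#' Bar chart of percent retained per fragment, coloured by notification
#' flag, with the RED threshold drawn as a dashed line.
#'
#' @param object A `merge_run` object.
#' @param trimmed_pct_threshold Threshold line to draw (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.merge_run <- function(object, trimmed_pct_threshold = 50, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$order), y = .data$percent_retained, fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = trimmed_pct_threshold,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = FLAG_COLOURS) +
    ggplot2::labs(x = "fragment (merge order)", y = "% of read retained",
                  fill = "flag") +
    ggplot2::theme_minimal()
}

#' Plot the merge chain's overlap structure
#'
#' Shows, per pairwise merge, the overlap length and the number of
#' conflicting columns; expected-orientation merges are drawn solid.
#'
#' @param object A `merge_chain` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.merge_chain <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$merge),
                                   y = .data$overlap_len,
                                   alpha = .data$orientation)) +
    ggplot2::geom_col(fill = "#37474f") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_conflicts),
                       vjust = -0.4, alpha = 1) +
    ggplot2::scale_alpha_manual(values = c(CORRECT = 1, CHECK = 0.45)) +
    ggplot2::labs(x = "merge", y = "overlap length (nt)",
                  alpha = "orientation",
                  caption = "label: conflicting columns") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL
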