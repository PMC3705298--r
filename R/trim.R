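# Sliding-window quality trimming of chromatogram ends.

#' Trim poor-quality chromatogram ends
#'
#' A window of `window` consecutive bases is slid inwards from each end of
#' the read until every quality score inside the window is at least
#' `threshold`; everything outside the first such window on each side is
#' trimmed. The entire first passing window is retained. A read in which no
#' window passes (including reads shorter than the window that contain any
#' failing base) trims to length zero, which is an error: no merge is
#' performed for such a read.
#'
#' @param chromatogram A `chromatogram` from [read_abif()], or any list with
#'   elements `bases` (or `sequence`) and `qualities`.
#' @param window Trim window: number of consecutive bases that must pass
#'   (default 10).
#' @param threshold Trim threshold: minimum Phred-like quality (default 20).
#' @return An object of class `trim_result`: list with `record` (list of
#'   `id`, `sequence`), `qualities` (scores of the kept bases),
#'   `left_trimmed`, `right_trimmed`, `original_length`, `percent_retained`
#'   and `flag` (`NA` until [assign_flag()] is applied).
#' @examples
#' ch <- list(bases = "ACGTACGT", qualities = c(5, 5, 30, 30, 30, 30, 30, 5),
#'            name = "ex")
#' trim_quality(ch, window = 2, threshold = 20)
#' @export
trim_quality <- function(chromatogram, window = 10L, threshold = 20L) {
  window <- as.integer(window)
  threshold <- as.integer(threshold)
  stopifnot(window >= 1L, threshold >= 0L)
  bases <- chromatogram$bases %||% chromatogram$sequence
  q <- as.integer(chromatogram$qualities)
  n <- length(q)
  stopifnot(n >= 1L, nchar(bases) == n)

  ok <- q >= threshold
  if (n < window) {
    ends <- if (all(ok)) n else integer(0)
    window_eff <- n
  } else {
    runsum <- stats::filter(as.integer(ok), rep(1L, window), sides = 1)
    ends <- which(!is.na(runsum) & runsum == window)
    window_eff <- window
  }
  if (length(ends) == 0L) {
    stop("trimmed to length zero; no merge performed", call. = FALSE)
  }
  left <- min(ends) - window_eff    # bases removed from the 5' end
  right <- n - max(ends)            # bases removed from the 3' end
  kept <- substr(bases, left + 1L, n - right)

  structure(
    list(
      record = list(id = chromatogram$name %||% "chromatogram", sequence = kept),
      qualities = q[(left + 1L):(n - right)],
      left_trimmed = left,
      right_trimmed = right,
      original_length = n,
      percent_retained = 100 * nchar(kept) / n,
      flag = NA_character_
    ),
    class = "trim_result"
  )
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf(
    "<trim_result> %s: kept %d/%d bases (%.1f%%), trimmed %d (5') + %d (3')%s\n",
    x$record$id, nchar(x$record$sequence), x$original_length,
    x$percent_retained, x$left_trimmed, x$right_trimmed,
    if (is.na(x$flag)) "" else paste0(", flag ", x$flag)))
  invisible(x)
}

#' Assign a notification flag to a trimmed fragment
#'
#' Mirrors the tool's output icons: `RED` when the trimmed read retains less
#' than `trimmed_pct_threshold` percent of its original length, else
#' `YELLOW` when it is shorter than `warning_length` bases, else `GREEN`.
#' FASTA inputs are never trimmed and are flagged `BLUE` upstream. Flags are
#' advisory only: flagged fragments are still merged.
#'
#' @param result A `trim_result` from [trim_quality()].
#' @param warning_length Short-amplicon warning length in bases (default 200).
#' @param trimmed_pct_threshold Minimum percentage of the original length
#'   that must be retained (default 50).
#' @return One of `"GREEN"`, `"YELLOW"`, `"RED"`.
#' @export
assign_flag <- function(result, warning_length = 200L,
                        trimmed_pct_threshold = 50) {
  len <- nchar(result$record$sequence)
  if (result$percent_retained < trimmed_pct_threshold) return("RED")
  if (len < warning_length) return("YELLOW")
  "GREEN"
}
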