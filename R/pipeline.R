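# End-to-end run: load ordered fragments, trim, orient, chain-merge,
# slide, reference-check, and write reports plus a ZIP archive.

#' Detect an input fragment's file type from its name
#'
#' `.ab1` means a chromatogram; `.fa`/`.fasta`/`.fsa` mean FASTA; a `.txt`
#' file is accepted as FASTA when it starts with `>`.
#'
#' @param path File path.
#' @return `"AB1"` or `"FASTA"`.
#' @export
detect_type <- function(path) {
  ext <- tolower(sub("^.*\\.", "", basename(path)))
  if (ext == "ab1") return("AB1")
  if (ext %in% c("fa", "fasta", "fsa")) return("FASTA")
  if (ext == "txt" && file.exists(path)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 1L && startsWith(trimws(first), ">")) return("FASTA")
  }
  stop("cannot detect type of ", basename(path),
       " (specify type explicitly)", call. = FALSE)
}

#' Load, trim and orient an ordered fragment set
#'
#' For each row of `fragments` (in merge order): AB1 chromatograms are
#' read, quality-trimmed with their per-fragment window/threshold and
#' their IDs annotated with the trim parameters; FASTA fragments are used
#' verbatim (never trimmed) and flagged `BLUE` with 100% retained. Reverse
#' and/or complement flags are then applied.
#'
#' @param fragments Data frame with column `path` and optional columns
#'   `type` (`"AB1"`/`"FASTA"`, default auto-detected), `window`,
#'   `threshold` (AB1 trim parameters, defaults 10/20), `reverse`,
#'   `complement` (defaults `FALSE`).
#' @param warning_length,trimmed_pct_threshold Flag thresholds, see
#'   [assign_flag()].
#' @return A tibble, one row per fragment in order: `order`, `name`,
#'   `type`, `id`, `sequence`, `qualities` (list), `original_length`,
#'   `trimmed_length`, `left_trimmed`, `right_trimmed`,
#'   `percent_retained`, `flag`.
#' @export
prepare_fragments <- function(fragments, warning_length = 200L,
                              trimmed_pct_threshold = 50) {
  stopifnot(is.data.frame(fragments), nrow(fragments) >= 1L,
            "path" %in% names(fragments))
  n <- nrow(fragments)
  type <- if ("type" %in% names(fragments)) fragments$type else rep(NA, n)
  window <- if ("window" %in% names(fragments)) fragments$window else rep(10L, n)
  threshold <- if ("threshold" %in% names(fragments)) fragments$threshold else rep(20L, n)
  rev_flag <- if ("reverse" %in% names(fragments)) fragments$reverse else rep(FALSE, n)
  comp_flag <- if ("complement" %in% names(fragments)) fragments$complement else rep(FALSE, n)

  rows <- lapply(seq_len(n), function(i) {
    ftype <- if (is.na(type[i]) || !nzchar(type[i])) detect_type(fragments$path[i]) else toupper(type[i])
    untrimmed <- NULL
    if (ftype == "AB1") {
      ch <- read_abif(fragments$path[i])
      untrimmed <- ch$bases
      tr <- tryCatch(trim_quality(ch, window[i], threshold[i]),
                     error = function(e) e)
      if (inherits(tr, "error")) stop("fragment ", i, " (", ch$name, "): ",
                                      conditionMessage(tr), call. = FALSE)
      seq <- tr$record$sequence
      qual <- tr$qualities
      id <- annotate_trimmed_id(ch$name, window[i], threshold[i])
      flag <- assign_flag(tr, warning_length, trimmed_pct_threshold)
      stats <- list(orig = tr$original_length, left = tr$left_trimmed,
                    right = tr$right_trimmed, pct = tr$percent_retained)
      name <- ch$name
    } else {
      rec <- read_fasta(fragments$path[i])[1, ]
      seq <- rec$sequence
      qual <- NULL
      id <- rec$id
      flag <- "BLUE"
      stats <- list(orig = nchar(seq), left = 0L, right = 0L, pct = 100)
      name <- rec$id
      untrimmed <- seq
    }
    if (isTRUE(rev_flag[i])) {
      seq <- seq_reverse(seq)
      qual <- rev(qual)
    }
    if (isTRUE(comp_flag[i])) seq <- seq_complement(seq)
    tibble::tibble(
      order = i, name = name, type = ftype, id = id, sequence = seq,
      untrimmed_sequence = untrimmed,
      qualities = list(qual), original_length = stats$orig,
      trimmed_length = nchar(seq), left_trimmed = stats$left,
      right_trimmed = stats$right, percent_retained = stats$pct, flag = flag)
  })
  dplyr::bind_rows(rows)
}

#' Run the full fragment-merging pipeline
#'
#' Loads the ordered fragments, trims and orients them
#' ([prepare_fragments()]), merges them sequentially ([merge_chain()]),
#' optionally rotates a circular assembly to a landmark motif
#' ([seq_slide()]) and checks the result against reference sequences
#' ([check_against_references()]). When `outdir` is given, all reports are
#' written there and bundled into a ZIP archive (chromatogram inputs
#' excluded).
#'
#' @param fragments Fragment table, see [prepare_fragments()]. 2-12 rows.
#' @param warning_length Short-amplicon warning length (default 200).
#' @param trimmed_pct_threshold Minimum percent retained before the RED
#'   flag (default 50).
#' @param merged_id Optional FASTA ID for the merged sequence; defaults to
#'   the first fragment's ID.
#' @param slide_motif,slide_position Optional circular rotation: after
#'   merging, rotate so `slide_motif` starts at `slide_position`.
#' @param reference Optional path to a FASTA file of reference sequences.
#' @param params An [alignment_params()] object.
#' @param max_merged_length Warn when the merged length exceeds this
#'   (default 100000).
#' @param outdir Optional output directory; created if needed.
#' @param archive Write the ZIP archive (default `TRUE`; only when
#'   `outdir` is given).
#' @param stamp Run timestamp used as the archive's folder name; defaults
#'   to the current time formatted `YYYYMMDD-HHMMSS`.
#' @return An object of class `merge_run`: list with `fragments` (prepared
#'   tibble), `chain` (`merge_chain`), `merged` (final record after any
#'   slide), `slide` (motif/position/applied), `ref_check` (or `NULL`),
#'   `files` (written files), `archive` (ZIP path or `NULL`).
#' @export
run_merge <- function(fragments, warning_length = 200L,
                      trimmed_pct_threshold = 50, merged_id = NULL,
                      slide_motif = NULL, slide_position = 1L,
                      reference = NULL, params = alignment_params(),
                      max_merged_length = 100000L, outdir = NULL,
                      archive = TRUE, stamp = NULL) {
  if (nrow(fragments) < 2L) stop("need at least two fragments", call. = FALSE)
  if (nrow(fragments) > 12L) stop("too many fragments", call. = FALSE)

  prep <- prepare_fragments(fragments, warning_length, trimmed_pct_threshold)
  for (i in which(prep$flag %in% c("YELLOW", "RED"))) {
    warning("fragment ", i, " (", prep$name[i], ") flagged ", prep$flag[i],
            call. = FALSE)
  }

  chain <- merge_chain(prep[, c("id", "sequence")], prep$qualities, params,
                       max_merged_length = max_merged_length)

  final_id <- merged_sequence_id(merged_id, prep$name[1])  # ID as submitted
  merged_seq <- chain$final$sequence
  slide <- NULL
  if (!is.null(slide_motif)) {
    slid <- tryCatch(seq_slide(merged_seq, slide_motif, slide_position),
                     error = function(e) e)
    if (inherits(slid, "error")) {
      warning(conditionMessage(slid), "; merged sequence left unrotated",
              call. = FALSE)
      slide <- list(motif = slide_motif, position = slide_position,
                    applied = FALSE)
    } else {
      merged_seq <- slid
      slide <- list(motif = slide_motif, position = slide_position,
                    applied = TRUE)
    }
  }
  merged <- list(id = final_id, sequence = merged_seq)

  refcheck <- NULL
  refs <- NULL
  if (!is.null(reference)) {
    refs <- read_fasta(reference)
    refcheck <- check_against_references(merged, refs, params)
  }

  run <- structure(
    list(fragments = prep, chain = chain, merged = merged, slide = slide,
         ref_check = refcheck, refs = refs, reference_path = reference,
         files = character(0), archive = NULL),
    class = "merge_run"
  )
  if (!is.null(outdir)) {
    run <- write_run_outputs(run, outdir, archive = archive, stamp = stamp)
  }
  run
}

#' @export
print.merge_run <- function(x, ...) {
  cat(sprintf("<merge_run> %d fragments -> %d nt merged sequence '%s'\n",
              nrow(x$fragments), nchar(x$merged$sequence), x$merged$id))
  cat("flags:", paste(x$fragments$flag, collapse = " "), "\n")
  if (!is.null(x$slide)) {
    cat(sprintf("slide: motif %s to position %d (%s)\n", x$slide$motif,
                x$slide$position,
                if (x$slide$applied) "applied" else "not applied"))
  }
  if (!is.null(x$ref_check)) {
    cat(sprintf("reference check: %d matches / %d mismatches\n",
                x$ref_check$n_matches, x$ref_check$n_mismatches))
  }
  if (!is.null(x$archive)) cat("archive:", x$archive, "\n")
  invisible(x)
}

# Render one pairwise merge report ("outFile") as text.
format_merge_report <- function(rep, index, width = 60L) {
  out <- c(sprintf("Merge %d", index),
           sprintf("score: %.1f", rep$score),
           sprintf("overlap: %d nt", rep$overlap_len),
           sprintf("orientation: %s", rep$orientation), "",
           "Alignment:")
  len <- nchar(rep$aligned_a)
  for (start in seq(1L, len, by = width)) {
    end <- min(start + width - 1L, len)
    sa <- substr(rep$aligned_a, start, end)
    sb <- substr(rep$aligned_b, start, end)
    marks <- paste(ifelse(chars(sa) != "-" & chars(sb) != "-" &
                            toupper(chars(sa)) == toupper(chars(sb)), "|", " "),
                   collapse = "")
    out <- c(out, sprintf("a %8d %s", start, sa),
             sprintf("  %8s %s", "", marks),
             sprintf("b %8d %s", start, sb), "")
  }
  out <- c(out, sprintf("Conflicts: %d", nrow(rep$conflicts)))
  if (nrow(rep$conflicts) > 0L) {
    out <- c(out, "position\tbase_a\tbase_b\tchosen\trule",
             sprintf("%d\t%s\t%s\t%s\t%s", rep$conflicts$merged_position,
                     rep$conflicts$base_a, rep$conflicts$base_b,
                     rep$conflicts$chosen, rep$conflicts$rule))
  }
  out
}

#' Write all pipeline outputs and the ZIP archive
#'
#' Writes, into `outdir`: the untrimmed input sequences, the trimmed
#' inputs (`ToMerge*`), the final merged sequence (`Merge0_*`), one
#' `outFile*` report per pairwise merge, the per-fragment summary
#' (`fragments.tsv`), the reference file with unaligned and aligned
#' merged+reference sequences (when a reference was given), a `run.log`
#' and a `README.txt` describing every file — then bundles everything
#' except chromatograms into `merge-archive.zip`, under a folder named
#' with the run timestamp.
#'
#' @param run A `merge_run` object.
#' @param outdir Output directory.
#' @param archive Also write the ZIP archive (default `TRUE`).
#' @param stamp Timestamp string; default `format(Sys.time(),
#'   "%Y%m%d-%H%M%S")`.
#' @return The `merge_run` with `files` and `archive` filled in.
#' @export
write_run_outputs <- function(run, outdir, archive = TRUE, stamp = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stamp <- stamp %||% format(Sys.time(), "%Y%m%d-%H%M%S")
  prep <- run$fragments
  files <- character(0)
  desc <- character(0)
  add <- function(path, what) {
    files <<- c(files, path); desc <<- c(desc, what)
  }

  # untrimmed input sequence data (chromatograms themselves stay out)
  for (i in seq_len(nrow(prep))) {
    p <- file.path(outdir, sprintf("Input%02d_%s.fasta", i, prep$name[i]))
    write_fasta(tibble::tibble(id = prep$name[i],
                               sequence = prep$untrimmed_sequence[i]), p)
    add(p, sprintf("untrimmed input sequence of fragment %d (%s)", i,
                   prep$type[i]))
  }

  # trimmed, oriented fragments entering the merge
  for (i in seq_len(nrow(prep))) {
    p <- file.path(outdir, sprintf("ToMerge%02d_%s.fasta", i, prep$name[i]))
    write_fasta(tibble::tibble(id = prep$id[i], sequence = prep$sequence[i]), p)
    add(p, sprintf("trimmed/oriented fragment %d entering merge", i))
  }

  # per-fragment summary
  summ <- dplyr::select(prep, "order", "name", "type", "original_length",
                        "trimmed_length", "left_trimmed", "right_trimmed",
                        "percent_retained", "flag")
  p <- file.path(outdir, "fragments.tsv")
  utils::write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
  add(p, "per-fragment summary (order, lengths, trim counts, flag)")

  # per-merge reports
  for (k in seq_along(run$chain$merges)) {
    p <- file.path(outdir, sprintf("outFile%02d.txt", k))
    writeLines(format_merge_report(run$chain$merges[[k]], k), p)
    add(p, sprintf("detailed report of merge %d", k))
  }

  # final merged sequence
  p <- file.path(outdir, sprintf("Merge0_%s.fasta",
                                 gsub("[^A-Za-z0-9._-]", "_", run$merged$id)))
  write_fasta(tibble::tibble(id = run$merged$id, sequence = run$merged$sequence), p)
  add(p, "final merged sequence")

  # reference check
  if (!is.null(run$ref_check)) {
    p <- file.path(outdir, "reference.fasta")
    write_fasta(run$refs, p)
    add(p, "reference sequences as supplied")
    p <- file.path(outdir, "merged_plus_reference_unaligned.fasta")
    write_fasta(tibble::tibble(
      id = c(run$merged$id, run$refs$id),
      sequence = c(run$merged$sequence, run$refs$sequence)), p)
    add(p, "merged + reference sequences, unaligned")
    p <- file.path(outdir, "merged_plus_reference_aligned.fasta")
    write_fasta(tibble::tibble(id = names(run$ref_check$rows),
                               sequence = unname(run$ref_check$rows)), p)
    add(p, "merged + reference sequences, aligned (FASTA)")
    p <- file.path(outdir, "reference_alignment.txt")
    writeLines(format_ref_check(run$ref_check), p)
    add(p, "merged vs reference alignment with match line and counts")
  }

  # run log
  p <- file.path(outdir, "run.log")
  log_lines <- c(
    sprintf("run %s", stamp),
    sprintf("fragments: %d; merges: %d", nrow(prep),
            length(run$chain$merges)),
    sprintf("fragment %d (%s): flag %s, %.1f%% retained", prep$order,
            prep$name, prep$flag, prep$percent_retained),
    if (!is.null(run$slide)) {
      sprintf("slide motif %s to position %d: %s", run$slide$motif,
              run$slide$position,
              if (run$slide$applied) "applied" else "NOT applied")
    },
    sprintf("merged length: %d nt", nchar(run$merged$sequence)))
  writeLines(log_lines, p)
  add(p, "run log (flags and warnings)")

  # README describing every file
  readme <- file.path(outdir, "README.txt")
  writeLines(c(
    sprintf("Fragment merge run %s", stamp),
    "", "Files in this archive:", "",
    sprintf("%-45s %s", basename(files), desc),
    sprintf("%-45s %s", "README.txt", "this file")), readme)
  files <- c(files, readme)

  run$files <- files
  if (archive) {
    zip_path <- file.path(outdir, "merge-archive.zip")
    keep <- files[!grepl("\\.ab1$", files, ignore.case = TRUE)]
    write_zip(zip_path, keep, prefix = stamp)
    run$archive <- zip_path
  }
  run
}
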