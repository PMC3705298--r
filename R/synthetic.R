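# Synthetic genomes, fragment plans and AB1/FASTA fixtures.
#
# Emulates the kind of input the tool was built for: a small (viral-scale)
# genome sequenced as 2-12 ordered overlapping Sanger amplicons, each read
# carrying low-quality junk at both ends. Reads get a quality profile that
# ramps linearly from `end_quality` up to `plateau_quality`; bases whose
# ramp quality is below 20 are random junk, so default trimming (window
# 10, threshold 20) removes exactly the junk and leaves the genuine
# genomic core. No peak-level trace data or substitution/indel error model
# is simulated beyond an optional substitution injector used to exercise
# conflict reporting.

#' Simulate a random genome
#'
#' Uniform-random ACGT sequence, optionally with a landmark motif planted
#' at a given position and guaranteed unique (the sequence is redrawn if
#' the motif occurs elsewhere by chance).
#'
#' @param length Genome length in nucleotides.
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @param motif Optional motif to plant (e.g. `"GAATTC"`).
#' @param motif_pos 1-based position at which to plant the motif.
#' @param id FASTA ID for the genome.
#' @return A list with `id` and `sequence`.
#' @export
simulate_genome <- function(length, seed, motif = NULL, motif_pos = 1L,
                            id = "genome") {
  stopifnot(length >= 1L)
  if (!is.null(motif)) {
    motif <- toupper(motif)
    stopifnot(motif_pos >= 1L)
    if (nchar(motif) > length || motif_pos + nchar(motif) - 1L > length) {
      stop("motif does not fit in genome", call. = FALSE)
    }
  }
  with_seed(seed, {
    for (try in 1:100) {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      if (is.null(motif)) return(list(id = id, sequence = s))
      substr(s, motif_pos, motif_pos + nchar(motif) - 1L) <- motif
      hits <- gregexpr(motif, paste0(s, substr(s, 1L, nchar(motif) - 1L)),
                       fixed = TRUE)[[1]]
      hits <- hits[hits > 0 & hits <= length]
      if (length(hits) == 1L) return(list(id = id, sequence = s))
    }
    stop("motif placement failed", call. = FALSE)
  })
}

#' Describe how to cut a genome into overlapping sequencing fragments
#'
#' @param n_fragments Number of fragments (2-12).
#' @param overlap_range Two integers: min and max overlap (nt) between
#'   consecutive fragments.
#' @param circular If `TRUE` the genome is treated as circular and the
#'   fragment set starts at a random rotation, so assembly recovers a
#'   rotation of the genome.
#' @param revcomp If `TRUE`, every second fragment is stored
#'   reverse-complemented with its `reverse`/`complement` flags set, as
#'   when amplicons are sequenced in both directions.
#' @param plateau_quality,end_quality,ramp_length Quality profile: scores
#'   ramp linearly from `end_quality` to `plateau_quality` over
#'   `ramp_length` bases at each read end, then hold at the plateau.
#' @param error_rate Per-base substitution probability inside overlap
#'   cores, to exercise conflict reporting (default 0 = error-free).
#' @param seed Integer seed covering all of the plan's randomness.
#' @return A list of class `fragment_plan`.
#' @export
fragment_plan <- function(n_fragments = 6L, overlap_range = c(30L, 60L),
                          circular = FALSE, revcomp = FALSE,
                          plateau_quality = 40L, end_quality = 2L,
                          ramp_length = 30L, error_rate = 0,
                          seed = 1L) {
  stopifnot(n_fragments >= 2L, n_fragments <= 12L,
            length(overlap_range) == 2L, overlap_range[1] >= 1L,
            overlap_range[1] <= overlap_range[2],
            plateau_quality >= 20L, end_quality >= 0L, end_quality < 20L,
            ramp_length >= 0L, error_rate >= 0, error_rate < 1)
  structure(
    list(n_fragments = as.integer(n_fragments),
         overlap_range = as.integer(overlap_range),
         circular = isTRUE(circular), revcomp = isTRUE(revcomp),
         plateau_quality = as.integer(plateau_quality),
         end_quality = as.integer(end_quality),
         ramp_length = as.integer(ramp_length),
         error_rate = error_rate, seed = as.integer(seed)),
    class = "fragment_plan"
  )
}

random_bases <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Cut a genome into overlapping chromatogram-like fragments
#'
#' Tiling: the genome (rotated randomly first if the plan is circular) is
#' split at roughly equal cut points; each fragment extends past its cut
#' point by an overlap drawn from `overlap_range`, so consecutive
#' fragments share that many genomic bases. Each read is the genomic core
#' flanked by random junk whose quality sits below 20 under the plan's
#' ramp, so default trimming recovers the core exactly.
#'
#' @param genome A list or one-row data frame with `id` and `sequence`.
#' @param plan A [fragment_plan()].
#' @return A tibble with one row per fragment in merge order: `order`,
#'   `id`, `sequence` (the raw read, junk included), `qualities`
#'   (list-column), `reverse`, `complement` (flags that restore the
#'   original orientation), `core_start`, `core_end` (coordinates of the
#'   genuine genomic core in the possibly rotated genome). The rotated
#'   genome the fragments tile is attached as attribute `"truth"`.
#' @export
fragment_genome <- function(genome, plan) {
  genome <- as_seq_record(genome, "genome")
  L <- nchar(genome$sequence)
  n <- plan$n_fragments
  with_seed(plan$seed, {
    g <- genome$sequence
    if (plan$circular) {
      rot <- sample.int(L, 1L) - 1L
      if (rot > 0L) g <- paste0(substr(g, rot + 1L, L), substr(g, 1L, rot))
    }
    cuts <- round(seq(0L, L, length.out = n + 1L))
    overlaps <- sample(seq(plan$overlap_range[1], plan$overlap_range[2]),
                       n - 1L, replace = TRUE)
    starts <- cuts[1:n] + 1L
    ends <- pmin(c(cuts[2:n] + overlaps, L), L)
    seg <- diff(cuts)
    # an overlap longer than the next fragment's own span would nest
    # fragments instead of tiling the genome
    if (any(ends <= starts) || any(starts[-1] > ends[-n]) ||
        any(overlaps > seg[-1])) {
      stop("cannot tile genome", call. = FALSE)
    }

    ramp <- if (plan$ramp_length > 0L) {
      as.integer(round(seq(plan$end_quality, plan$plateau_quality,
                           length.out = plan$ramp_length)))
    } else integer(0)
    junk_len <- sum(ramp < 20L)

    rows <- lapply(seq_len(n), function(i) {
      core <- substr(g, starts[i], ends[i])
      if (plan$error_rate > 0) {
        cc <- chars(core)
        hit <- which(stats::runif(length(cc)) < plan$error_rate)
        for (h in hit) {
          cc[h] <- sample(setdiff(c("A", "C", "G", "T"), toupper(cc[h])), 1L)
        }
        core <- paste(cc, collapse = "")
      }
      read <- paste0(random_bases(junk_len), core, random_bases(junk_len))
      core_len <- nchar(core)
      qual <- c(ramp, rep(plan$plateau_quality,
                          max(0L, core_len - 2L * (plan$ramp_length - junk_len))),
                rev(ramp))
      stopifnot(length(qual) == nchar(read))
      rc <- plan$revcomp && i %% 2L == 0L
      if (rc) {
        read <- seq_revcomp(read)
        qual <- rev(qual)
      }
      tibble::tibble(
        order = i, id = sprintf("frag%02d", i), sequence = read,
        qualities = list(as.integer(qual)), reverse = rc, complement = rc,
        core_start = starts[i], core_end = ends[i])
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- list(id = genome$id, sequence = g)
    out
  })
}

#' Write a fragment set to AB1 (or FASTA) files
#'
#' Materializes [fragment_genome()] output as input files for
#' [run_merge()], plus a tab-separated manifest of ground-truth
#' coordinates.
#'
#' @param frags Tibble from [fragment_genome()].
#' @param dir Output directory (created if needed).
#' @param format `"ab1"` (default) or `"fasta"`. FASTA fragments are
#'   written pre-trimmed (core only) since FASTA inputs are never trimmed.
#' @return A tibble usable as the `fragments` argument of [run_merge()]:
#'   `path`, `type`, `window`, `threshold`, `reverse`, `complement`.
#' @export
write_fragment_files <- function(frags, dir, format = c("ab1", "fasta")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(frags))
  for (i in seq_len(nrow(frags))) {
    if (format == "ab1") {
      paths[i] <- file.path(dir, paste0(frags$id[i], ".ab1"))
      write_abif_fixture(frags$sequence[i], frags$qualities[[i]], paths[i])
    } else {
      paths[i] <- file.path(dir, paste0(frags$id[i], ".fasta"))
      q <- frags$qualities[[i]]
      keep <- range(which(q >= 20L))
      write_fasta(tibble::tibble(
        id = frags$id[i],
        sequence = substr(frags$sequence[i], keep[1], keep[2])), paths[i])
    }
  }
  manifest <- dplyr::select(frags, -"sequence", -"qualities")
  manifest$path <- paths
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tibble::tibble(
    path = paths,
    type = if (format == "ab1") "AB1" else "FASTA",
    window = 10L, threshold = 20L,
    reverse = frags$reverse, complement = frags$complement)
}
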