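# ABIF (AB1) trace reading and minimal fixture writing.
#
# The ABIF container is a 4-byte "ABIF" magic, a 2-byte version, and a
# 28-byte "tdir" directory entry pointing at a table of further 28-byte
# entries. All integers are big-endian. Base calls live in the PBAS entry
# (char array) and per-base quality scores in PCON (byte array); entry
# number 1 holds the edited calls, number 2 the raw basecaller output.

ABIF_ENTRY_SIZE <- 28L

be_uint <- function(raw, offset, size) {
  b <- as.integer(raw[(offset + 1L):(offset + size)])
  sum(b * 256^((size - 1):0))
}

be_raw <- function(value, size) {
  out <- raw(size)
  for (k in size:1) {
    out[k] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

parse_dir_entry <- function(raw, offset) {
  list(
    name = rawToChar(raw[(offset + 1L):(offset + 4L)]),
    number = be_uint(raw, offset + 4L, 4L),
    elem_type = be_uint(raw, offset + 8L, 2L),
    elem_size = be_uint(raw, offset + 10L, 2L),
    n_elem = be_uint(raw, offset + 12L, 4L),
    data_size = be_uint(raw, offset + 16L, 4L),
    data_offset_field = offset + 20L,
    data_offset = be_uint(raw, offset + 20L, 4L)
  )
}

entry_data <- function(raw, entry) {
  # entries of 4 bytes or fewer store their data inline in the offset field
  start <- if (entry$data_size <= 4L) entry$data_offset_field else entry$data_offset
  raw[(start + 1L):(start + entry$data_size)]
}

#' Read an AB1 chromatogram
#'
#' Extracts the base calls and per-base quality scores from an ABIF trace
#' file. Edited entries (entry number 1) are preferred over the raw
#' basecaller entries (number 2) when both are present. Ambiguity codes in
#' the base calls are preserved verbatim; no re-basecalling is performed.
#'
#' @param path Path to an `.ab1` file.
#' @return An object of class `chromatogram`: a list with elements `name`
#'   (file stem), `bases` (nucleotide string), `qualities` (integer vector,
#'   one score per base) and `source_path`.
#' @examples
#' f <- write_abif_fixture("ACGT", c(10, 20, 30, 40), tempfile(fileext = ".ab1"))
#' read_abif(f)
#' @export
read_abif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 34L || rawToChar(raw[1:4]) != "ABIF") {
    stop("not an ABIF file: ", path, call. = FALSE)
  }
  tdir <- parse_dir_entry(raw, 6L)
  n <- tdir$n_elem
  entries <- lapply(seq_len(n) - 1L, function(k) {
    parse_dir_entry(raw, tdir$data_offset + k * ABIF_ENTRY_SIZE)
  })
  pick <- function(tag) {
    hits <- Filter(function(e) e$name == tag, entries)
    if (length(hits) == 0L) return(NULL)
    nums <- vapply(hits, function(e) e$number, numeric(1))
    hits[[which.min(nums)]]
  }
  pbas <- pick("PBAS")
  pcon <- pick("PCON")
  if (is.null(pbas) || is.null(pcon)) {
    stop("incomplete trace (missing PBAS or PCON entry): ", path, call. = FALSE)
  }
  bases <- rawToChar(entry_data(raw, pbas))
  qualities <- as.integer(entry_data(raw, pcon))
  if (nchar(bases) != length(qualities)) {
    stop("corrupt trace (base call / quality length mismatch): ", path,
         call. = FALSE)
  }
  structure(
    list(name = sub("\\.[^.]*$", "", basename(path)), bases = bases,
         qualities = qualities, source_path = path),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d bases, median quality %g\n",
              x$name, nchar(x$bases), stats::median(x$qualities)))
  invisible(x)
}

#' Write a minimal AB1 fixture
#'
#' Writes a syntactically valid ABIF file containing only the entries
#' [read_abif()] consumes (header, directory, PBAS.1 base calls, PCON.1
#' quality scores); no electropherogram trace data is emitted. Intended for
#' building test inputs from simulated reads.
#'
#' @param bases Nucleotide string.
#' @param qualities Integer vector of Phred-like scores in 0-62, one per base.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abif_fixture <- function(bases, qualities, path) {
  qualities <- as.integer(qualities)
  if (nchar(bases) != length(qualities)) {
    stop("bases/qualities length mismatch", call. = FALSE)
  }
  if (any(qualities < 0L | qualities > 62L)) {
    stop("qualities must be within 0-62", call. = FALSE)
  }
  n <- length(qualities)

  dir_entry <- function(tag, number, elem_type, elem_size, n_elem, data_size,
                        offset_field) {
    c(charToRaw(tag), be_raw(number, 4L), be_raw(elem_type, 2L),
      be_raw(elem_size, 2L), be_raw(n_elem, 4L), be_raw(data_size, 4L),
      offset_field, be_raw(0L, 4L))
  }
  inline <- function(data) c(data, raw(4L - length(data)))

  header_len <- 128L
  pbas_data <- charToRaw(bases)
  pcon_data <- as.raw(qualities)
  pbas_off <- header_len
  pcon_off <- pbas_off + if (n > 4L) n else 0L
  dir_off <- pcon_off + if (n > 4L) n else 0L

  entries <- c(
    dir_entry("PBAS", 1L, 2L, 1L, n, n,
              if (n <= 4L) inline(pbas_data) else be_raw(pbas_off, 4L)),
    dir_entry("PCON", 1L, 1L, 1L, n, n,
              if (n <= 4L) inline(pcon_data) else be_raw(pcon_off, 4L))
  )
  tdir <- dir_entry("tdir", 1L, 1023L, ABIF_ENTRY_SIZE, 2L,
                    2L * ABIF_ENTRY_SIZE, be_raw(dir_off, 4L))
  header <- c(charToRaw("ABIF"), be_raw(101L, 2L), tdir)
  header <- c(header, raw(header_len - length(header)))

  body <- if (n > 4L) c(pbas_data, pcon_data) else raw(0)
  writeBin(c(header, body, entries), path)
  invisible(path)
}
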