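# Minimal ZIP archive writer (stored entries, no compression).
#
# Written natively so the pipeline has no external archiver dependency;
# output is readable by standard unzip tools. Entry timestamps are fixed
# so archives with identical contents are byte-identical.

zip_u <- function(value, size) {
  out <- raw(size)
  for (k in seq_len(size)) {
    out[k] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

#' Write a ZIP archive of files
#'
#' Stores each file uncompressed under `prefix/<name>` inside the archive.
#'
#' @param zipfile Output archive path.
#' @param files Character vector of file paths to include.
#' @param prefix Folder name inside the archive (e.g. the run timestamp).
#' @return `zipfile`, invisibly.
#' @export
write_zip <- function(zipfile, files, prefix = "") {
  stopifnot(length(files) >= 1L, all(file.exists(files)))
  con <- file(zipfile, "wb")
  on.exit(close(con))
  dos_time <- zip_u(0L, 2L)           # fixed midnight
  dos_date <- zip_u(bitwOr(bitwShiftL(2026L - 1980L, 9L), bitwOr(bitwShiftL(1L, 5L), 1L)), 2L)

  offsets <- integer(length(files))
  names_in <- if (nzchar(prefix)) {
    file.path(prefix, basename(files))
  } else {
    basename(files)
  }
  offset <- 0L
  central <- list()
  for (k in seq_along(files)) {
    data <- readBin(files[k], "raw", file.size(files[k]))
    crc <- cpp_crc32(data)
    name <- charToRaw(names_in[k])
    local <- c(zip_u(0x04034b50, 4L), zip_u(20L, 2L), zip_u(0L, 2L),
               zip_u(0L, 2L), dos_time, dos_date, zip_u(crc, 4L),
               zip_u(length(data), 4L), zip_u(length(data), 4L),
               zip_u(length(name), 2L), zip_u(0L, 2L), name)
    writeBin(c(local, data), con)
    offsets[k] <- offset
    offset <- offset + length(local) + length(data)
    central[[k]] <- c(zip_u(0x02014b50, 4L), zip_u(20L, 2L), zip_u(20L, 2L),
                      zip_u(0L, 2L), zip_u(0L, 2L), dos_time, dos_date,
                      zip_u(crc, 4L), zip_u(length(data), 4L),
                      zip_u(length(data), 4L), zip_u(length(name), 2L),
                      zip_u(0L, 2L), zip_u(0L, 2L), zip_u(0L, 2L),
                      zip_u(0L, 2L), zip_u(0L, 4L), zip_u(offsets[k], 4L),
                      name)
  }
  cd <- do.call(c, central)
  writeBin(cd, con)
  eocd <- c(zip_u(0x06054b50, 4L), zip_u(0L, 2L), zip_u(0L, 2L),
            zip_u(length(files), 2L), zip_u(length(files), 2L),
            zip_u(length(cd), 4L), zip_u(offset, 4L), zip_u(0L, 2L))
  writeBin(eocd, con)
  invisible(zipfile)
}
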