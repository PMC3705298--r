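# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force sliding-window trim: test every window position directly.
# Returns c(first_kept, last_kept) 1-based, or NULL if nothing survives.
trim_oracle <- function(q, w, t) {
  n <- length(q)
  if (n < w) {
    if (all(q >= t)) return(c(1L, n)) else return(NULL)
  }
  pass <- vapply(seq_len(n - w + 1L),
                 function(i) all(q[i:(i + w - 1L)] >= t), logical(1))
  starts <- which(pass)
  if (length(starts) == 0L) return(NULL)
  c(min(starts), max(starts) + w - 1L)
}

# Exhaustive alignment-score oracle: walk every monotone alignment path
# (diagonal D, gap-in-b X, gap-in-a Y) by plain recursion, charging each
# gap run open + (k - 1) * ext except the alignment's first and last runs
# when they are gap runs (free end gaps). No memoization, so it stays
# independent of the DP; feasible for sequences up to ~8 nt.
align_score_oracle <- function(a, b, params = alignment_params()) {
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  M <- params$matrix; go <- params$gap_open; ge <- params$gap_extend
  best <- -Inf
  # prev: previous move ("" at start); run_cost: cost charged so far for
  # the current gap run; leading: current run is the alignment's first run
  rec <- function(i, j, prev, score, run_cost, leading) {
    if (i == la && j == lb) {
      final <- if (prev == "X" || prev == "Y") score + run_cost else score
      if (final > best) best <<- final
      return(invisible())
    }
    if (i < la && j < lb) {
      rec(i + 1L, j + 1L, "D", score + M[av[i + 1L], bv[j + 1L]], 0, FALSE)
    }
    if (i < la) {
      if (prev == "X") {
        cost <- if (leading) 0 else ge
        rec(i + 1L, j, "X", score - cost, run_cost + cost, leading)
      } else {
        new_run_leading <- prev == ""
        cost <- if (new_run_leading) 0 else go
        rec(i + 1L, j, "X", score - cost, cost, new_run_leading)
      }
    }
    if (j < lb) {
      if (prev == "Y") {
        cost <- if (leading) 0 else ge
        rec(i, j + 1L, "Y", score - cost, run_cost + cost, leading)
      } else {
        new_run_leading <- prev == ""
        cost <- if (new_run_leading) 0 else go
        rec(i, j + 1L, "Y", score - cost, cost, new_run_leading)
      }
    }
  }
  rec(0L, 0L, "", 0, 0, FALSE)
  best
}

# Independent byte-level ABIF re-parse (readBin-based, no package code).
parse_abif_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  stopifnot(magic == "ABIF")
  readBin(con, "integer", 1L, size = 2L, endian = "big")  # version
  read_entry <- function() {
    name <- readChar(con, 4L, useBytes = TRUE)
    number <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    readBin(con, "integer", 2L, size = 2L, endian = "big")  # type, elem size
    n_elem <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    data_size <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    offset_bytes <- readBin(con, "raw", 4L)
    readBin(con, "raw", 4L)  # data handle
    list(name = name, number = number, n_elem = n_elem,
         data_size = data_size, offset_bytes = offset_bytes)
  }
  tdir <- read_entry()
  dir_off <- sum(as.integer(tdir$offset_bytes) * 256^(3:0))
  seek(con, dir_off)
  entries <- lapply(seq_len(tdir$n_elem), function(k) read_entry())
  get_data <- function(e) {
    if (e$data_size <= 4L) return(e$offset_bytes[seq_len(e$data_size)])
    seek(con, sum(as.integer(e$offset_bytes) * 256^(3:0)))
    readBin(con, "raw", e$data_size)
  }
  out <- list()
  for (e in entries) out[[paste0(e$name, e$number)]] <- get_data(e)
  out
}

# Slice a known genome string into n overlapping fragments (pure string
# arithmetic, independent of the synthetic module).
slice_genome <- function(genome, n, overlap) {
  L <- nchar(genome)
  cuts <- round(seq(0, L, length.out = n + 1))
  lapply(seq_len(n), function(i) {
    substr(genome, cuts[i] + 1, min(cuts[i + 1] + overlap, L))
  })
}

# Rejection-sample a pair of sequences sharing no k-mer.
no_shared_kmer_pair <- function(len_a, len_b, k = 4L) {
  kmers <- function(s) {
    if (nchar(s) < k) return(character(0))
    vapply(seq_len(nchar(s) - k + 1L), function(i) substr(s, i, i + k - 1L),
           character(1))
  }
  repeat {
    a <- random_dna(len_a)
    b <- random_dna(len_b)
    if (length(intersect(kmers(a), kmers(b))) == 0L) return(list(a = a, b = b))
  }
}
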