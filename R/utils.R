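# internal helpers

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normalize a sequence input (character, list(id, sequence), or one-row
# data frame) into list(id, sequence).
as_seq_record <- function(x, default_id = "seq") {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    return(list(id = default_id, sequence = x))
  }
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(list(id = as.character(x$id[[1]]), sequence = as.character(x$sequence[[1]])))
  }
  if (is.list(x) && !is.null(x$sequence)) {
    return(list(id = as.character(x$id %||% default_id),
                sequence = as.character(x$sequence)))
  }
  stop("cannot interpret input as a sequence record", call. = FALSE)
}
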