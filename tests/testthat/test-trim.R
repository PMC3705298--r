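make_chrom <- function(q, bases = random_dna(length(q)), name = "t") {
  list(bases = bases, qualities = q, name = name)
}

test_that("trim keeps everything when nothing is below threshold", {
  tr <- trim_quality(make_chrom(rep(30L, 100)), window = 10, threshold = 20)
  expect_equal(tr$left_trimmed, 0L)
  expect_equal(tr$right_trimmed, 0L)
  expect_equal(tr$percent_retained, 100)
})

test_that("trim boundaries match direct window enumeration", {
  q <- c(5, 5, 25, 25, 25, 25, 5)
  tr <- trim_quality(make_chrom(q), window = 2, threshold = 20)
  expect_equal(tr$left_trimmed, 2L)
  expect_equal(tr$right_trimmed, 1L)
  expect_equal(nchar(tr$record$sequence), 4L)
  keep <- trim_oracle(q, 2L, 20L)
  expect_equal(c(tr$left_trimmed + 1L, length(q) - tr$right_trimmed), keep)
})

test_that("reads trimmed to length zero raise the no-merge error", {
  expect_error(trim_quality(make_chrom(rep(10L, 100))),
               "trimmed to length zero")
  # shorter than the window with a failing base
  expect_error(trim_quality(make_chrom(c(30L, 5L, 30L)), window = 10),
               "trimmed to length zero")
  # shorter than the window but all passing: kept whole
  tr <- trim_quality(make_chrom(rep(30L, 5)), window = 10, threshold = 20)
  expect_equal(nchar(tr$record$sequence), 5L)
})

test_that("trim agrees with the brute-force oracle on random short reads", {
  set.seed(42)
  for (case in 1:300) {
    n <- sample(1:50, 1)
    q <- sample(0:45, n, replace = TRUE)
    w <- sample(1:12, 1)
    t <- sample(0:40, 1)
    ch <- make_chrom(q)
    keep <- trim_oracle(q, w, t)
    res <- tryCatch(trim_quality(ch, w, t), error = function(e) NULL)
    if (is.null(keep)) {
      expect_null(res)
    } else {
      expect_false(is.null(res))
      expect_equal(res$left_trimmed, keep[1] - 1L)
      expect_equal(res$right_trimmed, n - keep[2])
      # conservation
      expect_equal(res$left_trimmed + nchar(res$record$sequence) +
                     res$right_trimmed, n)
      expect_equal(res$record$sequence, substr(ch$bases, keep[1], keep[2]))
      expect_equal(res$percent_retained,
                   100 * nchar(res$record$sequence) / n)
    }
  }
})

test_that("stricter parameters never lengthen the kept region", {
  set.seed(9)
  for (case in 1:50) {
    n <- sample(20:60, 1)
    q <- sample(0:45, n, replace = TRUE)
    ch <- make_chrom(q)
    kept_len <- function(w, t) {
      r <- tryCatch(trim_quality(ch, w, t), error = function(e) NULL)
      if (is.null(r)) 0L else nchar(r$record$sequence)
    }
    expect_lte(kept_len(5, 30), kept_len(5, 20))   # raise threshold
    expect_lte(kept_len(10, 20), kept_len(5, 20))  # widen window
  }
})

test_that("flags follow the warning-length and percent thresholds", {
  fake_result <- function(orig, kept) {
    structure(list(record = list(id = "x", sequence = strrep("A", kept)),
                   original_length = orig,
                   percent_retained = 100 * kept / orig),
              class = "trim_result")
  }
  expect_equal(assign_flag(fake_result(700, 650)), "GREEN")
  expect_equal(assign_flag(fake_result(300, 180)), "YELLOW")
  # RED takes precedence when both conditions hold
  expect_equal(assign_flag(fake_result(700, 180)), "RED")
  # boundary: exactly the warning length / exactly the percent cutoff pass
  expect_equal(assign_flag(fake_result(300, 200)), "GREEN")
  expect_equal(assign_flag(fake_result(400, 200)), "GREEN")
})
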