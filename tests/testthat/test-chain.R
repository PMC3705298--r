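frag_tbl <- function(seqs) {
  tibble::tibble(id = paste0("f", seq_along(seqs)), sequence = unlist(seqs))
}

test_that("a chain of sliced fragments reconstructs the source string", {
  genome <- "ACGTACGTAAGGCCTTAACGGT"
  frags <- list(substr(genome, 1, 10), substr(genome, 5, 16),
                substr(genome, 11, 22))
  ch <- merge_chain(frag_tbl(frags))
  expect_equal(ch$final$sequence, genome)
  expect_length(ch$merges, 2L)
})

test_that("n fragments always produce n - 1 merges", {
  set.seed(53)
  genome <- random_dna(3000)
  for (n in c(2L, 5L, 12L)) {
    frags <- slice_genome(genome, n, overlap = 30)
    ch <- merge_chain(frag_tbl(frags))
    expect_length(ch$merges, n - 1L)
    expect_equal(ch$fragment_count, n)
    expect_equal(ch$final$sequence, genome)
    # each merge output feeds the next merge
    if (n > 2L) {
      for (k in 2:(n - 1L)) {
        al_prev <- ch$merges[[k - 1L]]$merged$sequence
        expect_equal(gsub("-", "", ch$merges[[k]]$aligned_a), al_prev)
      }
    }
  }
})

test_that("fragment count bounds and empty fragments are enforced", {
  expect_error(merge_chain(frag_tbl(list("ACGT"))), "at least two")
  seqs <- slice_genome(random_dna(4000), 13, 25)
  expect_error(merge_chain(frag_tbl(seqs)), "too many fragments")
  ch <- merge_chain(frag_tbl(seqs), max_fragments = 13)  # cap is configurable
  expect_length(ch$merges, 12L)
  expect_error(merge_chain(frag_tbl(list("ACGT", "", "GGTT"))),
               "empty fragment")
})

test_that("random genomes are recovered exactly across sizes and counts", {
  set.seed(59)
  for (case in 1:6) {
    L <- sample(1000:10000, 1)
    n <- sample(2:12, 1)
    genome <- random_dna(L)
    frags <- slice_genome(genome, n, overlap = sample(20:60, 1))
    ch <- merge_chain(frag_tbl(frags))
    expect_equal(ch$final$sequence, genome)
    expect_true(all(vapply(ch$merges, function(m) m$orientation,
                           character(1)) == "CORRECT"))
  }
})

test_that("circular fragment sets recover a rotation of the genome", {
  g <- simulate_genome(3200, seed = 61, motif = "GAATTC", motif_pos = 815)
  plan <- fragment_plan(n_fragments = 7, overlap_range = c(25, 50),
                        circular = TRUE, seed = 67)
  fr <- fragment_genome(g, plan)
  trimmed <- lapply(seq_len(nrow(fr)), function(i) {
    q <- fr$qualities[[i]]
    r <- range(which(q >= 20))
    substr(fr$sequence[i], r[1], r[2])
  })
  ch <- merge_chain(frag_tbl(trimmed))
  out <- ch$final$sequence
  expect_equal(nchar(out), 3200L)
  expect_true(grepl(out, paste0(g$sequence, g$sequence), fixed = TRUE))
  # rotating to the landmark recovers the genome in standard orientation
  expect_equal(seq_slide(out, "GAATTC", 815), g$sequence)
})

test_that("overlong merged sequences warn but do not fail", {
  set.seed(71)
  genome <- random_dna(2000)
  frags <- slice_genome(genome, 3, 30)
  expect_warning(merge_chain(frag_tbl(frags), max_merged_length = 1000),
                 "exceeds")
})

test_that("tidiers summarise the chain", {
  set.seed(73)
  genome <- random_dna(1500)
  ch <- merge_chain(frag_tbl(slice_genome(genome, 4, 30)))
  td <- tidy(ch)
  expect_equal(nrow(td), 3L)
  expect_equal(td$merge, 1:3)
  expect_true(all(td$orientation == "CORRECT"))
  g <- glance(ch)
  expect_equal(g$fragment_count, 4L)
  expect_equal(g$final_length, 1500L)
  expect_true(g$all_correct)
})
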