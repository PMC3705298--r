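test_that("exact suffix/prefix overlaps merge by string arithmetic", {
  mp <- merge_pair("ACGTACGTAA", "GTAACGGTT")
  expect_equal(mp$merged$sequence, "ACGTACGTAACGGTT")
  expect_equal(nchar(mp$merged$sequence), 10 + 9 - 4)
  expect_equal(mp$overlap_len, 4L)
  expect_equal(nrow(mp$conflicts), 0L)
  expect_equal(mp$orientation, "CORRECT")

  # longer seeded exact overlaps, verified against substring construction
  set.seed(13)
  for (case in 1:10) {
    left <- random_dna(sample(100:300, 1))
    ov <- random_dna(sample(25:60, 1))
    right <- random_dna(sample(100:300, 1))
    a <- paste0(left, ov)
    b <- paste0(ov, right)
    mp <- merge_pair(a, b)
    expect_equal(mp$merged$sequence, paste0(left, ov, right))
    expect_equal(mp$orientation, "CORRECT")
    expect_equal(nrow(mp$conflicts), 0L)
  }
})

test_that("merging a sequence with itself is the identity", {
  set.seed(17)
  a <- random_dna(200)
  mp <- merge_pair(a, a)
  expect_equal(mp$merged$sequence, a)
  expect_equal(mp$overlap_len, 200L)
  expect_equal(nrow(mp$conflicts), 0L)
  expect_equal(mp$orientation, "CORRECT")
})

test_that("non-overlapping sequences concatenate with one shared base", {
  # disjoint alphabets: no shared k-mer for any k
  set.seed(19)
  a <- random_dna(150, c("A", "C"))
  b <- random_dna(120, c("G", "T"))
  mp <- merge_pair(a, b)
  expect_equal(nchar(mp$merged$sequence), 150 + 120 - 1)
  expect_equal(mp$overlap_len, 1L)
  expect_equal(mp$orientation, "CHECK")

  # short random ACGT pair with no shared 4-mer (longer random pairs
  # share a 4-mer almost surely, so the precondition is only attainable
  # at small lengths)
  pair <- no_shared_kmer_pair(18, 20, k = 4)
  mp2 <- merge_pair(pair$a, pair$b)
  expect_equal(nchar(mp2$merged$sequence), 18 + 20 - 1)
})

test_that("conflicts are resolved by position when qualities are absent", {
  set.seed(29)
  ov <- random_dna(60)
  a <- paste0(random_dna(100), ov)                 # conflict base near a's 3' end
  b <- paste0(ov, random_dna(100))
  k <- 57L                                         # 3 bases from a's 3' end
  truth <- substr(ov, k, k)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  substr(a, 100 + k, 100 + k) <- wrong
  mp <- merge_pair(a, b)
  expect_equal(nrow(mp$conflicts), 1L)
  expect_equal(mp$conflicts$chosen, truth)         # b's base wins
  expect_equal(mp$conflicts$rule, "position")
  expect_equal(mp$merged$sequence, paste0(substr(a, 1, 100), ov,
                                          substr(b, 61, 160)))
})

test_that("conflicts prefer the higher-quality base when scores exist", {
  set.seed(37)
  ov <- random_dna(60)
  a <- paste0(random_dna(50), ov)
  b <- paste0(ov, random_dna(50))
  k <- 30L
  truth <- substr(ov, k, k)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  substr(a, 50 + k, 50 + k) <- wrong
  qa <- rep(40L, nchar(a)); qb <- rep(30L, nchar(b))
  mp <- merge_pair(a, b, qual_a = qa, qual_b = qb)
  expect_equal(nrow(mp$conflicts), 1L)
  expect_equal(mp$conflicts$chosen, wrong)   # a's (wrong) base has higher quality
  expect_equal(mp$conflicts$rule, "quality")

  mp2 <- merge_pair(a, b, qual_a = qb, qual_b = qa)
  expect_equal(mp2$conflicts$chosen, truth)
})

test_that("merge invariants hold on random overlapping pairs", {
  set.seed(41)
  for (case in 1:15) {
    ov <- random_dna(sample(20:60, 1))
    a <- paste0(random_dna(sample(10:200, 1)), ov)
    b <- paste0(ov, random_dna(sample(10:200, 1)))
    # sprinkle substitutions into b's copy of the overlap
    nmut <- sample(0:3, 1)
    pos <- sample(seq_len(nchar(ov)), nmut)
    for (p in pos) {
      substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(b, p, p))[sample(3, 1)]
    }
    mp <- merge_pair(a, b)
    len <- nchar(mp$merged$sequence)
    expect_gte(len, max(nchar(a), nchar(b)))
    expect_lte(len, nchar(a) + nchar(b))
    # conflict count equals mismatching overlap columns
    ca <- strsplit(mp$aligned_a, "")[[1]]
    cb <- strsplit(mp$aligned_b, "")[[1]]
    both <- ca != "-" & cb != "-"
    expect_equal(nrow(mp$conflicts), sum(both & ca != cb))
    expect_equal(sum(both), mp$overlap_len)
    # chosen base always comes from one of the two fragments
    if (nrow(mp$conflicts) > 0) {
      expect_true(all(mp$conflicts$chosen == mp$conflicts$base_a |
                        mp$conflicts$chosen == mp$conflicts$base_b))
    }
  }
})

test_that("reversed-orientation overlaps are flagged for checking", {
  set.seed(43)
  ov <- random_dna(40)
  a <- paste0(ov, random_dna(100))   # overlap at a's START
  b <- paste0(random_dna(100), ov)   # overlap at b's END
  mp <- merge_pair(a, b)
  expect_equal(mp$orientation, "CHECK")
})

test_that("empty fragments are rejected", {
  expect_error(merge_pair("", "ACGT"), "empty fragment")
  expect_error(merge_pair("ACGT", ""), "empty fragment")
})
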