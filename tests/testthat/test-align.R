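strip_gaps <- function(s) gsub("-", "", s, fixed = TRUE)

test_that("identity and single-base alignments score as expected", {
  al <- align_overlap("ACGT", "ACGT")
  expect_equal(al$score, 20)
  expect_equal(al$aligned_a, "ACGT")
  expect_equal(al$aligned_b, "ACGT")

  al1 <- align_overlap("A", "A")
  expect_equal(al1$score, 5)
  expect_equal(nchar(al1$aligned_a), 1L)
})

test_that("dissimilar sequences stack with free end gaps", {
  al <- align_overlap("AAAA", "TTTT")
  expect_equal(al$score, align_score_oracle("AAAA", "TTTT"))
  expect_equal(strip_gaps(al$aligned_a), "AAAA")
  expect_equal(strip_gaps(al$aligned_b), "TTTT")
})

test_that("DP score equals exhaustive alignment enumeration", {
  params <- alignment_params()
  set.seed(23)
  cases <- c(
    list(list(a = "AAAA", b = "TTTT"),
         list(a = "ACACACAC", b = "CACA"),
         list(a = "ACGTACGT", b = "GTACGTAA")),
    lapply(1:12, function(i) {
      list(a = random_dna(sample(1:6, 1), c("A", "C")),
           b = random_dna(sample(1:6, 1), c("A", "C")))
    }),
    lapply(1:3, function(i) {
      list(a = random_dna(8, c("A", "C")), b = random_dna(8, c("A", "C")))
    })
  )
  for (cs in cases) {
    al <- align_overlap(cs$a, cs$b, params)
    expect_equal(al$score, align_score_oracle(cs$a, cs$b, params),
                 info = paste(cs$a, cs$b))
  }
})

test_that("gap-stripped aligned strings reproduce the inputs, case kept", {
  set.seed(31)
  for (case in 1:25) {
    a <- random_dna(sample(5:120, 1))
    b <- random_dna(sample(5:120, 1))
    # lowercase a stretch to check case restoration
    substr(a, 2, min(5, nchar(a))) <- tolower(substr(a, 2, min(5, nchar(a))))
    al <- align_overlap(a, b)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
    expect_equal(strip_gaps(al$aligned_a), a)
    expect_equal(strip_gaps(al$aligned_b), b)
  }
})

test_that("scores agree with an independent overlap aligner", {
  # Biostrings' free-end-gap ("overlap") aligner as external cross-check;
  # its gap cost is open + k*ext, so open is shifted to match ours.
  params <- alignment_params()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(77)
  for (case in 1:10) {
    core <- random_dna(sample(30:80, 1))
    a <- paste0(random_dna(sample(50:150, 1)), core)
    b <- paste0(core, random_dna(sample(50:150, 1)))
    if (case %% 3 == 0) {  # sometimes unrelated pairs
      a <- random_dna(60); b <- random_dna(60)
    }
    ours <- align_overlap(a, b, params)$score
    theirs <- Biostrings::pairwiseAlignment(
      a, b, type = "overlap", substitutionMatrix = mat,
      gapOpening = params$gap_open - params$gap_extend,
      gapExtension = params$gap_extend, scoreOnly = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("the IUPAC matrix averages ambiguity scores", {
  m <- iupac_score_matrix()
  expect_equal(m["A", "A"], 5)
  expect_equal(m["A", "T"], -4)
  expect_equal(m["A", "R"], 0.5)    # mean of +5 (A) and -4 (G)
  expect_equal(m["N", "N"], mean(c(5, rep(-4, 3), 5, rep(-4, 3),
                                   5, rep(-4, 3), 5, rep(-4, 3))))
  expect_true(isSymmetric(m))
})
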