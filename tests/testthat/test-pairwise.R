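test_that("self-alignment is gapless with the diagonal score", {
  s <- default_scheme()
  motif <- "NVVSHGTQDLLLT"
  aln <- global_align(motif, motif, s)
  expect_false(grepl("-", aln$aligned_a))
  chars <- strsplit(motif, "")[[1]]
  expect_equal(aln$raw_score, sum(s$matrix[cbind(chars, chars)]))
  expect_equal(unname(identity_similarity(aln, s)), c(100, 100))
  one <- global_align("A", "A", s)
  expect_equal(one$raw_score, s$matrix["A", "A"])
})

test_that("alignment scores match the brute-force enumeration oracle", {
  s <- scoring_scheme(default_scheme()$matrix, gap_open = 10, gap_extend = 1,
                      name = "test")
  set.seed(3)
  for (rep in 1:12) {
    a <- random_protein(sample(2:5, 1))
    b <- random_protein(sample(2:5, 1))
    expect_equal(global_align(a, b, s)$raw_score, brute_global_score(a, b, s),
                 info = paste(a, b))
    expect_equal(local_align(a, b, s)$raw_score, brute_local_score(a, b, s),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with the reference library implementation", {
  skip_if_not_installed("Biostrings")
  s <- default_scheme()
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(11)
  for (rep in 1:10) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    # reference convention: first gap position costs gapOpening + gapExtension
    ref_g <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = BLOSUM62,
      gapOpening = s$gap_open - s$gap_extend, gapExtension = s$gap_extend,
      type = "global", scoreOnly = TRUE)
    ref_l <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = BLOSUM62,
      gapOpening = s$gap_open - s$gap_extend, gapExtension = s$gap_extend,
      type = "local", scoreOnly = TRUE)
    expect_equal(global_align(a, b, s)$raw_score, ref_g)
    expect_equal(local_align(a, b, s)$raw_score, ref_l)
  }
})

test_that("alignment score is symmetric and alignments are consistent", {
  s <- default_scheme()
  set.seed(5)
  for (rep in 1:10) {
    a <- random_protein(30); b <- random_protein(25)
    for (mode in c(global_align, local_align)) {
      ab <- mode(a, b, s); ba <- mode(b, a, s)
      expect_equal(ab$raw_score, ba$raw_score)
      # removing gaps recovers the (sub)sequences; no gap/gap column
      ga <- gsub("-", "", ab$aligned_a)
      gb <- gsub("-", "", ab$aligned_b)
      expect_true(grepl(ga, a, fixed = TRUE))
      expect_true(grepl(gb, b, fixed = TRUE))
      cols <- cbind(strsplit(ab$aligned_a, "")[[1]],
                    strsplit(ab$aligned_b, "")[[1]])
      expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
    }
  }
})

test_that("local alignment finds a planted shared segment", {
  set.seed(9)
  core <- random_protein(30)
  a <- paste0(random_protein(40), core, random_protein(35))
  b <- paste0(random_protein(25), core, random_protein(50))
  aln <- local_align(a, b)
  expect_true(aln$a_span[1] <= 41 && aln$a_span[2] >= 70)
  expect_true(aln$b_span[1] <= 26 && aln$b_span[2] >= 55)
  # no positive-scoring residue pair => empty local alignment
  s <- default_scheme()
  expect_true(all(s$matrix["C", "W"] < 0))
  empty <- local_align("CCCC", "WWWW", s)
  expect_equal(empty$raw_score, 0)
  expect_equal(empty$a_span, c(0L, 0L))
  expect_equal(nchar(empty$aligned_a), 0L)
  # but when one positive pair exists, local score is at least that pair
  one <- local_align("CAC", "WAW", s)
  expect_gte(one$raw_score, s$matrix["A", "A"])
})

test_that("identity and similarity follow the full-length convention", {
  s <- default_scheme()
  aln <- global_align("AV", "AI", s)
  expect_true(s$matrix["V", "I"] > 0)
  expect_equal(unname(identity_similarity(aln, s)), c(50, 100))
  # gap columns count in the denominator only
  fake <- structure(list(aligned_a = "AAAAAAA--A", aligned_b = "AAAAA--GGA",
                         raw_score = 0, mode = "global",
                         a_span = c(1, 8), b_span = c(1, 8),
                         id_a = "x", id_b = "y"),
                    class = "pairwise_alignment")
  ident <- identity_similarity(fake, s)[["identity"]]
  expect_equal(ident, 100 * 6 / 10)
  expect_error(global_align("", "A"), "empty")
})

test_that("E-values follow the Karlin-Altschul closed form", {
  p <- ka_params(m = 100, n = 100, lambda = 0.267, K = 0.041)
  expect_equal(evalue(40, p), 0.041 * 100 * 100 * exp(-0.267 * 40))
  p2 <- ka_params(m = 100, n = 200, lambda = 0.267, K = 0.041)
  expect_equal(evalue(40, p2), 2 * evalue(40, p))   # linear in n
  expect_lt(evalue(60, p), evalue(40, p))           # decreasing in score
  expect_equal(evalue(1e6, p), 0)                   # limit
  expect_error(ka_params(m = 0, n = 10), "m")
})

test_that("substitution matrix I/O round-trips the bundled matrix", {
  path <- system.file("extdata", "BLOSUM62.txt", package = "jenscape")
  m <- read_score_matrix(path)
  expect_equal(dim(m), c(20L, 20L))
  expect_equal(m, t(m))
  expect_equal(m["V", "I"], 3L)
  expect_equal(m["W", "W"], 11L)
  expect_error(scoring_scheme(m, gap_open = 1, gap_extend = 2), "gap_open")
})
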