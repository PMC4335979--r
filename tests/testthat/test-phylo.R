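make_msa <- function(...) {
  rows <- c(...)
  multiple_alignment(paste0("s", seq_along(rows)), rows)
}

test_that("p-distances use pairwise deletion", {
  msa <- make_msa("AAAA", "AAAT", "A-AA")
  D <- p_distance_matrix(msa)
  expect_equal(D$d["s1", "s1"], 0)
  expect_equal(D$d["s1", "s2"], 0.25)
  expect_equal(D$d["s2", "s3"], 1 / 3)   # 3 comparable columns, 1 mismatch
  msa2 <- make_msa("A-AA", "AT-A")
  expect_equal(p_distance_matrix(msa2)$d[1, 2], 0)  # 2 comparable, 0 diff
  expect_error(p_distance_matrix(make_msa("A--", "-AA")), "no comparable")
})

test_that("distance corrections follow their closed forms and limits", {
  expect_equal(correct_distance(0, "poisson"), 0)
  expect_equal(correct_distance(0, "gamma", alpha = 0.5), 0)
  expect_equal(correct_distance(0.1, "poisson"), -log(0.9))
  expect_equal(correct_distance(0.3, "gamma", alpha = 1e6),
               correct_distance(0.3, "poisson"), tolerance = 1e-6)
  p <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(correct_distance(p, "poisson")) > 0))
  expect_true(all(diff(correct_distance(p, "gamma", alpha = 0.7)) > 0))
  expect_true(all(correct_distance(p, "gamma", alpha = 2) >=
                    correct_distance(p, "poisson")))
  expect_error(correct_distance(1, "poisson"), "saturated")
  expect_error(correct_distance(0.995, "poisson"), "saturated")
  expect_equal(correct_distance(0.999, "poisson", saturation = "cap"), 6.907755,
               tolerance = 1e-6)
  expect_equal(correct_distance(0.99999999, "poisson", saturation = "cap",
                                max_distance = 10), 10)
})

test_that("NJ solves the three-taxon case exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(distance_matrix(d))
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 1)
  expect_equal(bl[["b"]], 1)
  expect_equal(bl[["c"]], 3)
  # two taxa: one path of total length d(a,b)
  d2 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- neighbor_joining(distance_matrix(d2))
  expect_equal(sum(tr2$edge.length), 5)
})

test_that("NJ and BioNJ are consistent on additive matrices", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    tr <- random_binary_tree(n)
    D <- additive_matrix(tr)
    nj_tree <- neighbor_joining(D)
    expect_equal(robinson_foulds(nj_tree, tr), 0)
    expect_equal(sum(nj_tree$edge.length), sum(tr$edge.length),
                 tolerance = 1e-9)
    bionj_tree <- bionj(D)
    expect_equal(robinson_foulds(bionj_tree, tr), 0)
  }
})

test_that("BioNJ equals NJ on three taxa and tracks it under noise", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(robinson_foulds(bionj(distance_matrix(d)),
                               neighbor_joining(distance_matrix(d))), 0)
  # on noisy additive matrices BioNJ should be no worse than NJ on average
  set.seed(31)
  wins <- 0L
  n_rep <- 60L
  for (rep in seq_len(n_rep)) {
    tr <- random_binary_tree(8)
    D <- additive_matrix(tr)
    noisy <- D$d * matrix(stats::runif(64, 0.98, 1.02), 8, 8)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    Dn <- distance_matrix(noisy)
    rf_nj <- robinson_foulds(neighbor_joining(Dn), tr)
    rf_bionj <- robinson_foulds(bionj(Dn), tr)
    if (rf_bionj <= rf_nj) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.5)
})

test_that("Robinson-Foulds matches explicit counts and the reference library", {
  t1 <- read_newick("((a,b),(c,(d,e)));")
  expect_equal(robinson_foulds(t1, t1), 0)
  t2 <- read_newick("((a,b),(d,(c,e)));")  # one NNI away
  expect_equal(robinson_foulds(t1, t2), 2)
  star <- read_newick("(a,b,c,d,e);")
  expect_equal(robinson_foulds(star, t1), 5 - 3)
  expect_error(robinson_foulds(t1, read_newick("((a,b),c);")), "leaf sets")
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (rep in 1:10) {
    x <- random_binary_tree(9); y <- random_binary_tree(9)
    expect_equal(robinson_foulds(x, y), phangorn::RF.dist(x, y))
  }
})

test_that("outgroup rooting splits the outgroup edge at its midpoint", {
  tr <- read_newick("((a:1,b:1):1,(c:1,d:2):1);")
  rooted <- root_with_outgroup(tr, "d")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  d_tip <- match("d", rooted$tip.label)
  expect_true(d_tip %in% kids)
  root_lens <- rooted$edge.length[rooted$edge[, 1] ==
                                    length(rooted$tip.label) + 1L]
  expect_equal(root_lens[1], root_lens[2])
  expect_equal(sum(root_lens), 2)
  # rooting then unrooting restores the unrooted topology
  expect_equal(robinson_foulds(ape::unroot(rooted), tr), 0)
  # an outgroup splitting a cherry is rejected
  expect_error(root_with_outgroup(tr, c("a", "c")), "monophyletic")
})

test_that("bootstrap supports behave at the extremes and are deterministic", {
  ids <- paste0("s", 1:6)
  # every column supports ((s1,s2,s3),(s4,s5,s6))
  block <- c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA",
             "TTTTTTTTTT", "TTTTTTTTTT", "CCCCCCCCCC")
  msa <- multiple_alignment(ids, block)
  bs <- bootstrap_support(msa, "nj", n_replicates = 20, seed = 2)
  expect_true(all(bs$supports == 100))
  set.seed(4)
  rows <- vapply(1:6, function(i) random_protein(40), "")
  msa2 <- multiple_alignment(ids, rows)
  b1 <- bootstrap_support(msa2, "nj", n_replicates = 25, seed = 5)
  b2 <- bootstrap_support(msa2, "nj", n_replicates = 25, seed = 5)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  b3 <- bootstrap_support(msa2, "nj", n_replicates = 1, seed = 6)
  expect_true(all(b3$supports %in% c(0, 100)))
})

test_that("bootstrap supports are invariant under leaf relabeling", {
  set.seed(8)
  rows <- vapply(1:5, function(i) random_protein(60), "")
  m1 <- multiple_alignment(paste0("x", 1:5), rows)
  m2 <- multiple_alignment(paste0("y", 5:1), rows)   # bijective relabeling
  b1 <- bootstrap_support(m1, "nj", n_replicates = 30, seed = 3)
  b2 <- bootstrap_support(m2, "nj", n_replicates = 30, seed = 3)
  expect_equal(sort(unname(b1$supports)), sort(unname(b2$supports)))
})
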