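test_that("species-tree simulation is deterministic with the right shape", {
  expect_error(simulate_species_tree(1), "at least 2")
  t2 <- simulate_species_tree(2, seed = 3)
  expect_equal(length(t2$tip.label), 2L)
  a <- simulate_species_tree(6, seed = 1)
  b <- simulate_species_tree(6, seed = 1)
  expect_identical(write_newick(a), write_newick(b))
  expect_false(identical(write_newick(a),
                         write_newick(simulate_species_tree(6, seed = 2))))
  big <- simulate_species_tree(50, seed = 7)
  expect_equal(length(big$tip.label), 50L)
  expect_equal(big$Nnode, 49L)            # 2n - 1 nodes in a rooted binary tree
  expect_true(all(big$edge.length > 0))
  # branch lengths follow the exponential mean
  lens <- simulate_species_tree(200, seed = 11)$edge.length
  expect_equal(mean(lens), 0.1, tolerance = 0.15)
})

test_that("gene-family simulation respects its degenerate limits", {
  tr <- simulate_species_tree(6, seed = 2)
  none <- simulate_gene_family(tr, simulation_config(
    n_species = 6, dup_rate = 0, loss_rate = 0, seed = 4))
  expect_equal(none$n_duplications + none$n_losses, 0)
  expect_equal(robinson_foulds(none$gene_tree, {
    tmp <- tr; tmp$tip.label <- paste0(tr$tip.label, "__1"); tmp
  }), 0)
  doomed <- simulate_gene_family(tr, simulation_config(
    n_species = 6, dup_rate = 0, loss_rate = 200, seed = 4))
  expect_true(doomed$extinct)
  expect_null(doomed$gene_tree)
  expect_true(all(doomed$events$event_type == "loss"))
  naked <- tr; naked$edge.length <- NULL
  expect_error(simulate_gene_family(naked, simulation_config()), "branch lengths")
})

test_that("duplication counts match the Poisson expectation along lineages", {
  tr <- simulate_species_tree(6, seed = 6)
  diffs <- vapply(seq_len(400), function(i) {
    truth <- simulate_gene_family(tr, simulation_config(
      n_species = 6, dup_rate = 0.5, loss_rate = 0, seed = 10000L + i))
    # with no losses, the total gene-lineage length is the pruned tree length
    L <- sum(truth$gene_tree$edge.length)
    truth$n_duplications - 0.5 * L
  }, 0)
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
})

test_that("sequence evolution obeys the 20-state model limits", {
  tr <- read_newick("(a__1:0,b__1:0);")
  cfg <- simulation_config(n_species = 2, seq_length = 50, subst_rate = 0,
                           n_decoys_per_species = 0)
  prot <- evolve_sequences(tr, cfg, species = c("a", "b"), seed = 1)
  expect_equal(prot$a[[1]]$residues, prot$b[[1]]$residues)
  # infinitely long branch: identity to the other leaf at the uniform 1/20
  tr2 <- read_newick("(a__1:0,b__1:1e6);")
  cfg2 <- simulation_config(n_species = 2, seq_length = 10000, subst_rate = 1,
                            n_decoys_per_species = 0)
  prot2 <- evolve_sequences(tr2, cfg2, species = c("a", "b"), seed = 2)
  pa <- strsplit(prot2$a[[1]]$residues, "")[[1]]
  pb <- strsplit(prot2$b[[1]]$residues, "")[[1]]
  expect_equal(mean(pa == pb), 1 / 20, tolerance = 0.15)
  # determinism: same seed, byte-identical proteomes
  again <- evolve_sequences(tr2, cfg2, species = c("a", "b"), seed = 2)
  expect_identical(vapply(again$b, `[[`, "", "residues"),
                   vapply(prot2$b, `[[`, "", "residues"))
})

test_that("pairwise p-distance follows the Jukes-Cantor-type closed form", {
  path <- 0.6
  tr <- read_newick(sprintf("(a__1:%g,b__1:%g);", path / 2, path / 2))
  cfg <- simulation_config(n_species = 2, seq_length = 10000, subst_rate = 1,
                           n_decoys_per_species = 0)
  prot <- evolve_sequences(tr, cfg, species = c("a", "b"), seed = 8)
  pa <- strsplit(prot$a[[1]]$residues, "")[[1]]
  pb <- strsplit(prot$b[[1]]$residues, "")[[1]]
  p_obs <- mean(pa != pb)
  p_exp <- 0.95 * (1 - exp(-(20 / 19) * path))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("consumption curves are exact when noiseless and reproducible", {
  t <- seq(0, 40, by = 2)
  truth <- consumption_truth("fumarate", c0 = 10, true_rate = 0.22, times = t)
  ts <- simulate_consumption_series(truth, seed = 1)
  expect_equal(ts$concentration, pmax(0, 10 - 0.22 * t))
  flat <- simulate_consumption_series(
    consumption_truth("malate", c0 = 5, true_rate = 0, times = t), seed = 1)
  expect_true(all(flat$concentration == 5))
  noisy1 <- simulate_consumption_series(
    consumption_truth("succinate", 10, 0.19, t, noise_sd = 0.05), seed = 9)
  noisy2 <- simulate_consumption_series(
    consumption_truth("succinate", 10, 0.19, t, noise_sd = 0.05), seed = 9)
  expect_identical(noisy1$concentration, noisy2$concentration)
  expect_true(all(noisy1$concentration >= 0))
  expect_error(consumption_truth("x", 10, 0.1, t, noise_sd = -1), "noise_sd")
})

test_that("two-regime curves change slope at the breakpoint", {
  t <- seq(0, 40, by = 2)
  truth <- consumption_truth("fumarate", c0 = 10, true_rate = 0.16, times = t,
                             breakpoint = 22, rate_after = 0.057)
  ts <- simulate_consumption_series(truth, seed = 1)
  before <- ts$concentration[t <= 22]
  after <- ts$concentration[t >= 22]
  expect_equal(unique(round(-diff(before) / 2, 10)), 0.16)
  expect_equal(unique(round(-diff(after) / 2, 10)), 0.057)
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(simulate_species_tree(5, seed = 99))
  after <- stats::runif(1)
  expect_identical(before, after)
})
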