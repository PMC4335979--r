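test_that("a congruent single-copy gene tree reconciles without events", {
  sp <- read_newick("((a,b),(c,d));")
  gt <- read_newick("((a__1,b__1),(c__1,d__1));")
  rec <- lca_reconcile(gt, sp)
  expect_equal(rec$n_duplications, 0)
  expect_equal(rec$n_losses, 0)
  expect_true(all(rec$events == "speciation"))
  rep <- scenario_report(rec)
  expect_true(all(rep$duplications == 0 & rep$losses == 0))
  expect_true(all(rep$entering == 1 & rep$leaving == 1))
})

test_that("canonical small cases give the textbook event counts", {
  sp <- read_newick("(a,b);")
  rec1 <- lca_reconcile(read_newick("(a__1,a__2);"), sp)
  expect_equal(rec1$n_duplications, 1)
  expect_equal(rec1$n_losses, 0)
  rec2 <- lca_reconcile(read_newick("(a__1,(a__2,b__1));"), sp)
  expect_equal(rec2$n_duplications, 1)
  expect_equal(rec2$n_losses, 1)
  # the loss sits on the b branch (the copy lost under the a__1 lineage)
  expect_equal(rec2$losses$species_branch, "b")
  rep <- scenario_report(rec2)
  expect_equal(rep$losses[rep$branch == "b"], 1)
  expect_equal(sum(rep$losses), 1)
  # oracle confirms no cheaper history exists
  orc <- recon_oracle(read_newick("(a__1,(a__2,b__1));"), sp,
                      leaf_map_from_names(c("a__1", "a__2", "b__1")))
  expect_equal(orc$min_total, 2)
  expect_equal(orc$min_duplications, 1)
})

test_that("LCA reconciliation equals the exhaustive minimum on random instances", {
  set.seed(17)
  n_checked <- 0L
  while (n_checked < 40L) {
    n_sp <- sample(2:5, 1)
    sp <- random_binary_tree(n_sp)
    sp$tip.label <- paste0("s", seq_len(n_sp))
    n_g <- sample(2:8, 1)
    gt <- random_binary_tree(n_g)
    gt$tip.label <- sprintf("s%d__%d", sample(n_sp, n_g, replace = TRUE),
                            seq_len(n_g))
    rec <- lca_reconcile(gt, sp)
    orc <- recon_oracle(gt, sp, leaf_map_from_names(gt$tip.label))
    expect_equal(rec$n_duplications + rec$n_losses, orc$min_total)
    expect_equal(rec$n_duplications, orc$min_duplications)
    n_checked <- n_checked + 1L
  }
})

test_that("reconciliation input validation catches bad trees and maps", {
  sp <- read_newick("((a,b),c);")
  gt <- read_newick("(a__1,b__1,c__1);")   # polytomy
  expect_error(lca_reconcile(gt, sp), "binary")
  gt2 <- read_newick("(a__1,(b__1,x__1));")
  expect_error(lca_reconcile(gt2, sp), "unknown species")
  gt3 <- read_newick("(a__1,(b__1,c__1));")
  expect_error(lca_reconcile(gt3, sp, leaf_map = c(a__1 = "a")), "unmapped")
})

test_that("clade summaries partition the global event counts", {
  set.seed(23)
  for (rep in 1:10) {
    sp <- random_binary_tree(5)
    sp$tip.label <- paste0("s", 1:5)
    gt <- random_binary_tree(7)
    gt$tip.label <- sprintf("s%d__%d", sample(5, 7, replace = TRUE), 1:7)
    rec <- lca_reconcile(gt, sp)
    whole <- clade_event_summary(rec, sp$tip.label)
    expect_equal(unname(whole[["duplications"]]), rec$n_duplications)
    expect_equal(unname(whole[["losses"]]), rec$n_losses)
    expect_equal(unname(whole[["total"]]), rec$n_duplications + rec$n_losses)
    # the two root subtrees partition all events
    root_kids <- sp$edge[sp$edge[, 1] == 6L, 2]
    parts <- lapply(root_kids, function(k) {
      tips <- if (k <= 5L) sp$tip.label[k] else
        ape::extract.clade(sp, k)$tip.label
      clade_event_summary(rec, if (length(tips) == 1L) tips else tips)
    })
    root_dups <- sum(rec$events == "duplication" &
                       rec$mapping[as.integer(names(rec$events))] == 6L)
    expect_equal(sum(vapply(parts, `[[`, 0, "total")) + root_dups,
                 unname(whole[["total"]]))
  }
  expect_error(clade_event_summary(
    lca_reconcile(read_newick("(a__1,b__1);"), read_newick("(a,b);")),
    "nope"), "unknown")
})

test_that("per-branch bookkeeping is consistent and ties out at the tips", {
  set.seed(29)
  for (rep in 1:15) {
    sp <- random_binary_tree(5)
    sp$tip.label <- paste0("s", 1:5)
    gt <- random_binary_tree(8)
    gt$tip.label <- sprintf("s%d__%d", sample(5, 8, replace = TRUE), 1:8)
    rec <- lca_reconcile(gt, sp)
    rep_tab <- scenario_report(rec)
    expect_true(all(rep_tab$leaving ==
                      rep_tab$entering + rep_tab$duplications - rep_tab$losses))
    # copies leaving a tip branch equal the genes mapped to that species
    for (tip in sp$tip.label) {
      expect_equal(rep_tab$leaving[rep_tab$branch == tip],
                   sum(leaf_map_from_names(gt$tip.label) == tip))
    }
    expect_equal(sum(rep_tab$duplications), rec$n_duplications)
    expect_equal(sum(rep_tab$losses), rec$n_losses)
  }
})

test_that("event annotation and ortholog constraints reflect the mapping", {
  sp <- read_newick("(a,b);")
  gt <- read_newick("(a__1,(a__2,b__1));")
  rec <- lca_reconcile(gt, sp)
  ann <- annotate_events(rec)
  expect_setequal(ann$node.label, c("D", "S"))
  expect_match(write_newick(ann), "D")
  # a__2/b__1 diverged at a speciation; a__1/a__2 at the duplication
  expect_true(check_ortholog_constraints(rec, rbind(c("a__2", "b__1"))))
  expect_warning(
    ok <- check_ortholog_constraints(rec, rbind(c("a__1", "a__2"))),
    "violate")
  expect_false(ok)
  expect_error(check_ortholog_constraints(rec, rbind(c("a__1", "zz"))),
               "unknown gene leaf")
})

test_that("parsimony recovers the simulated truth exactly on clean histories", {
  set.seed(37)
  n_clean <- 0L; n_tried <- 0L
  while (n_clean < 25L && n_tried < 400L) {
    n_tried <- n_tried + 1L
    sp <- simulate_species_tree(5, seed = 1000L + n_tried)
    truth <- simulate_gene_family(
      sp, simulation_config(n_species = 5, dup_rate = 0.6, loss_rate = 0.4,
                            seed = 2000L + n_tried))
    if (is.null(truth$gene_tree)) next
    rec <- lca_reconcile(truth$gene_tree, sp)
    # parsimony can never over-count the true history
    expect_lte(rec$n_duplications, truth$n_duplications)
    expect_lte(rec$n_duplications + rec$n_losses,
               truth$n_duplications + truth$n_losses)
    if (truth$clean_history) {
      n_clean <- n_clean + 1L
      expect_equal(rec$n_duplications, truth$n_duplications)
      expect_equal(rec$n_losses, truth$n_losses)
    }
  }
  expect_gte(n_clean, 25L)
})
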