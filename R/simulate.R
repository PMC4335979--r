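#' Configuration for the gene-family simulator
#'
#' Bundles the parameters of the forward birth-death gene-family process and
#' sequence evolution.  Defaults describe a moderately dynamic family in a
#' small clade: 6 species, duplication rate 0.3 and loss rate 0.1 events per
#' unit branch length, 250-residue proteins evolving at 0.2 substitutions
#' per site per unit branch length, embedded among 20 unrelated decoy
#' proteins per proteome.
#'
#' @param n_species number of species (>= 2).
#' @param dup_rate duplication rate per unit branch length (>= 0).
#' @param loss_rate loss rate per unit branch length (>= 0).
#' @param root_copies gene copies at the species-tree root (>= 1).
#' @param seq_length root protein length in residues.
#' @param subst_rate expected substitutions per site per unit branch length.
#' @param n_decoys_per_species unrelated background proteins per proteome.
#' @param branch_length_mean mean of the exponential species-tree branch
#'   lengths, substitutions per site (default 0.1).
#' @param seed integer seed; fully determines every simulator output.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 6L, dup_rate = 0.3, loss_rate = 0.1,
                              root_copies = 1L, seq_length = 250L,
                              subst_rate = 0.2, n_decoys_per_species = 20L,
                              branch_length_mean = 0.1, seed = 1L) {
  stopifnot(n_species >= 2L, dup_rate >= 0, loss_rate >= 0,
            root_copies >= 1L, seq_length >= 1L, subst_rate >= 0,
            n_decoys_per_species >= 0L, branch_length_mean > 0)
  structure(list(n_species = as.integer(n_species), dup_rate = dup_rate,
                 loss_rate = loss_rate, root_copies = as.integer(root_copies),
                 seq_length = as.integer(seq_length), subst_rate = subst_rate,
                 n_decoys_per_species = as.integer(n_decoys_per_species),
                 branch_length_mean = branch_length_mean,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a species tree
#'
#' Yule (uniform random splitting) topology with independent exponential
#' branch lengths.  Leaves are named `sp1 ... spN`.
#'
#' @param n_species number of leaves (>= 2).
#' @param seed integer seed.
#' @param branch_length_mean mean branch length (default 0.1
#'   substitutions/site).
#' @return a rooted binary [ape::phylo] tree.
#' @export
simulate_species_tree <- function(n_species, seed = 1L,
                                  branch_length_mean = 0.1) {
  if (n_species < 2L) stop("need at least 2 species", call. = FALSE)
  with_seed(seed, {
    # grow topology by splitting a uniformly chosen leaf
    kids <- list(c(2L, 3L))        # node 1 = root
    is_leaf <- c(FALSE, TRUE, TRUE)
    leaves <- c(2L, 3L)
    nxt <- 4L
    while (length(leaves) < n_species) {
      pick <- leaves[[sample.int(length(leaves), 1L)]]
      kids[[pick]] <- c(nxt, nxt + 1L)
      is_leaf[[pick]] <- FALSE
      is_leaf[nxt + 0:1] <- TRUE
      leaves <- c(setdiff(leaves, pick), nxt, nxt + 1L)
      nxt <- nxt + 2L
    }
    leaf_name <- integer()
    counter <- 0L
    build <- function(node) {
      len <- stats::rexp(1L, rate = 1 / branch_length_mean)
      if (is_leaf[[node]]) {
        counter <<- counter + 1L
        sprintf("sp%d:%.17g", counter, len)
      } else {
        ch <- kids[[node]]
        sprintf("(%s,%s):%.17g", build(ch[[1]]), build(ch[[2]]), len)
      }
    }
    ch <- kids[[1L]]
    txt <- sprintf("(%s,%s);", build(ch[[1]]), build(ch[[2]]))
    read_newick(txt)
  })
}

#' Simulate a gene family by birth-death along a species tree
#'
#' Each gene lineage traversing a species-tree branch of length t accrues
#' duplications and losses as competing Poisson processes with rates
#' `dup_rate * t` and `loss_rate * t`; duplications split the lineage in
#' place, losses terminate it, and surviving lineages at the leaves become
#' genes named `species__k`.  The pruned gene tree (extinct lineages
#' removed, unary nodes suppressed) is returned together with the complete
#' event list.
#'
#' The `clean_history` flag records whether the history is fully
#' recoverable by duplication-loss parsimony on the pruned tree: every
#' duplication left survivors on both sides, every speciation on at least
#' one side, and every lost lineage was created by a speciation (its loss is
#' then forced by the surviving sister lineage).  When the flag is TRUE,
#' [lca_reconcile()] recovers the exact event counts; otherwise parsimony
#' can only under-count.
#'
#' @param species_tree rooted binary [ape::phylo] with branch lengths.
#' @param config a [simulation_config()]; its `seed` drives the draws.
#' @return an object of class `gene_family_truth`: `species_tree`,
#'   `gene_tree` ([ape::phylo], or NULL when fewer than 2 genes survive),
#'   `genes` (data frame `gene`, `species`), `events` (data frame
#'   `event_type`, `species_branch`, `time`), `n_duplications`, `n_losses`,
#'   `clean_history`, `extinct`.
#' @export
simulate_gene_family <- function(species_tree, config) {
  stopifnot(inherits(species_tree, "phylo"),
            inherits(config, "simulation_config"))
  if (is.null(species_tree$edge.length)) {
    stop("species tree must have branch lengths", call. = FALSE)
  }
  if (!is_binary_rooted(species_tree) || !ape::is.rooted(species_tree)) {
    stop("species tree must be rooted and binary", call. = FALSE)
  }
  n_sp <- length(species_tree$tip.label)
  kids <- tree_children(species_tree)
  edge_len <- numeric(n_sp + species_tree$Nnode)
  edge_len[species_tree$edge[, 2]] <- species_tree$edge.length
  root <- n_sp + 1L

  events <- list()
  counters <- stats::setNames(integer(n_sp), species_tree$tip.label)
  lam <- config$dup_rate + config$loss_rate

  with_seed(config$seed, {
    # simulate one lineage from a point on the branch above `node`, with
    # `t_remain` branch length still to traverse; `parent_kind` names the
    # branching that created this lineage segment
    sim_edge <- function(node, t_remain, parent_kind) {
      used <- 0
      repeat {
        w <- if (lam > 0) stats::rexp(1L, lam) else Inf
        if (w < t_remain - used) {
          used <- used + w
          if (stats::runif(1L) < config$dup_rate / lam) {
            events[[length(events) + 1L]] <<- data.frame(
              event_type = "duplication",
              species_branch = node_name(species_tree, node),
              time = used, stringsAsFactors = FALSE)
            left <- sim_edge(node, t_remain - used, "duplication")
            right <- sim_edge(node, t_remain - used, "duplication")
            return(list(kind = "dup", branch = node, blen = used,
                        parent_kind = parent_kind,
                        children = list(left, right)))
          } else {
            events[[length(events) + 1L]] <<- data.frame(
              event_type = "loss",
              species_branch = node_name(species_tree, node),
              time = used, stringsAsFactors = FALSE)
            return(list(kind = "loss", branch = node, blen = used,
                        parent_kind = parent_kind))
          }
        } else {
          break
        }
      }
      blen <- t_remain
      if (node <= n_sp) {
        counters[[node]] <<- counters[[node]] + 1L
        return(list(kind = "leaf", branch = node, blen = blen,
                    parent_kind = parent_kind,
                    name = sprintf("%s__%d", species_tree$tip.label[[node]],
                                   counters[[node]]),
                    species = species_tree$tip.label[[node]]))
      }
      ch <- kids[[node]]
      list(kind = "spec", branch = node, blen = blen,
           parent_kind = parent_kind,
           children = list(sim_edge(ch[[1]], edge_len[[ch[[1]]]], "speciation"),
                           sim_edge(ch[[2]], edge_len[[ch[[2]]]], "speciation")))
    }
    ch <- kids[[root]]
    roots <- lapply(seq_len(config$root_copies), function(i) {
      list(kind = "spec", branch = root, blen = 0, parent_kind = "root",
           children = list(sim_edge(ch[[1]], edge_len[[ch[[1]]]], "speciation"),
                           sim_edge(ch[[2]], edge_len[[ch[[2]]]], "speciation")))
    })
    roots
  }) -> roots

  # --- recoverability of the history by DL parsimony on the pruned tree ---
  # The flag is a *sufficient* structural condition under which the LCA
  # reconciliation of the pruned gene tree reproduces the event counts
  # exactly:
  #   (1) every loss is "immediate": its lineage was created by a speciation
  #       and died without branching, so the surviving sister forces it;
  #   (2) every speciation has survivors on at least one side, and the root
  #       speciation on both sides (otherwise the pruned root's image drops
  #       below the species root and stem losses become invisible);
  #   (3) every duplication has survivors on both sides, and each copy's
  #       surviving descendants span the species node the duplication sits
  #       on (otherwise the duplication is pulled down the species tree and
  #       events above the pull-down point vanish).
  sp_par_full <- tree_parents(species_tree)
  sp_depth_full <- tree_depths(species_tree)
  sp_lca2 <- function(a, b) {
    while (a != b) {
      if (sp_depth_full[a] >= sp_depth_full[b]) a <- sp_par_full[a]
      else b <- sp_par_full[b]
    }
    a
  }
  surv_lca <- function(node) {
    # species-tree LCA of the species of surviving leaves; 0L when extinct
    if (node$kind == "leaf") {
      return(match(node$species, species_tree$tip.label))
    }
    if (node$kind == "loss") return(0L)
    imgs <- vapply(node$children, surv_lca, 0L)
    imgs <- imgs[imgs != 0L]
    if (length(imgs) == 0L) return(0L)
    Reduce(sp_lca2, imgs)
  }
  clean <- TRUE
  walk_clean <- function(node) {
    if (node$kind == "loss" && node$parent_kind != "speciation") {
      clean <<- FALSE
    }
    if (node$kind == "dup") {
      imgs <- vapply(node$children, surv_lca, 0L)
      if (any(imgs == 0L) || any(imgs != node$branch)) clean <<- FALSE
    }
    if (node$kind == "spec") {
      n_alive <- sum(vapply(node$children, surv_lca, 0L) != 0L)
      need <- if (node$parent_kind == "root") 2L else 1L
      if (n_alive < need) clean <<- FALSE
    }
    if (!is.null(node$children)) lapply(node$children, walk_clean)
    invisible(NULL)
  }
  lapply(roots, walk_clean)
  if (config$root_copies > 1L) clean <- FALSE  # joint origin not reconstructable

  # prune extinct lineages and suppress unary nodes
  prune <- function(node, acc_len) {
    if (node$kind == "loss") return(NULL)
    if (node$kind == "leaf") {
      return(list(name = node$name, species = node$species,
                  blen = acc_len + node$blen))
    }
    parts <- lapply(node$children, prune,
                    acc_len = 0)
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) {
      out <- parts[[1L]]
      out$blen <- out$blen + acc_len + node$blen
      return(out)
    }
    list(children = parts, blen = acc_len + node$blen)
  }
  pruned <- lapply(roots, prune, acc_len = 0)
  pruned <- pruned[!vapply(pruned, is.null, TRUE)]

  gene_list <- list()
  collect <- function(node) {
    if (!is.null(node$name)) {
      gene_list[[length(gene_list) + 1L]] <<- data.frame(
        gene = node$name, species = node$species, stringsAsFactors = FALSE)
    } else lapply(node$children, collect)
    invisible(NULL)
  }
  lapply(pruned, collect)
  genes <- if (length(gene_list)) do.call(rbind, gene_list) else
    data.frame(gene = character(), species = character(),
               stringsAsFactors = FALSE)

  to_newick <- function(node) {
    if (!is.null(node$name)) {
      return(sprintf("%s:%.17g", node$name, node$blen))
    }
    sprintf("(%s):%.17g",
            paste(vapply(node$children, to_newick, ""), collapse = ","),
            node$blen)
  }
  gene_tree <- NULL
  if (nrow(genes) >= 2L) {
    if (length(pruned) == 1L) {
      top <- pruned[[1L]]
      if (!is.null(top$name)) {
        gene_tree <- NULL  # a single gene: no tree
      } else {
        txt <- sprintf("(%s);",
                       paste(vapply(top$children, to_newick, ""),
                             collapse = ","))
        gene_tree <- read_newick(txt)
      }
    } else {
      txt <- sprintf("(%s);",
                     paste(vapply(pruned, to_newick, ""), collapse = ","))
      gene_tree <- read_newick(txt)
    }
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(event_type = character(), species_branch = character(),
               time = numeric(), stringsAsFactors = FALSE)
  structure(list(
    species_tree = species_tree,
    gene_tree = gene_tree,
    genes = genes,
    events = ev,
    n_duplications = sum(ev$event_type == "duplication"),
    n_losses = sum(ev$event_type == "loss"),
    clean_history = clean,
    extinct = nrow(genes) == 0L),
    class = "gene_family_truth")
}

#' @export
print.gene_family_truth <- function(x, ...) {
  cat(sprintf(
    "<gene_family_truth> %d genes in %d species; %d duplications, %d losses%s\n",
    nrow(x$genes), length(unique(x$genes$species)),
    x$n_duplications, x$n_losses,
    if (x$clean_history) " (clean history)" else ""))
  invisible(x)
}

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

#' Evolve protein sequences along a gene tree
#'
#' Sequences evolve under the 20-state equal-rates substitution model:
#' substitution events arrive at each site as a Poisson process with rate
#' `subst_rate` per unit branch length, each replacement drawn uniformly
#' from the 19 other residues.  Per branch the exact transition probability
#' is used, so multiple hits and back-substitutions are modelled and the
#' expected pairwise p-distance follows the 20-state closed form
#' `0.95 * (1 - exp(-(20/19) * subst_rate * path))`.
#' Decoy proteins (uniform random sequences with lengths
#' uniform in 200-800 residues) are appended to each proteome so that
#' homology screening has a realistic background.
#'
#' @param gene_tree an [ape::phylo] gene tree with `species__k` leaf names,
#'   or NULL for a family with no tree (no family sequences are produced).
#' @param config a [simulation_config()].
#' @param root_seq optional root residue string (length `seq_length`).
#' @param species character vector of all species tokens (decoys are
#'   generated for every species, including family-free ones).
#' @param seed integer seed (defaults to `config$seed + 1`).
#' @return named list: species token -> list of [seq_record()]s.
#' @export
evolve_sequences <- function(gene_tree, config, root_seq = NULL,
                             species = NULL,
                             seed = derive_seed(config$seed, "seq")) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$subst_rate < 0) stop("negative substitution rate", call. = FALSE)
  if (is.null(species)) {
    species <- if (!is.null(gene_tree)) {
      unique(sub("__[0-9]+$", "", gene_tree$tip.label))
    } else character()
  }
  with_seed(seed, {
    proteomes <- stats::setNames(
      replicate(length(species), list(), simplify = FALSE), species)
    if (!is.null(gene_tree)) {
      if (is.null(gene_tree$edge.length)) {
        stop("gene tree must have branch lengths", call. = FALSE)
      }
      if (is.null(root_seq)) {
        root_seq <- random_sequence(config$seq_length)
      } else if (nchar(root_seq) != config$seq_length) {
        stop("root_seq length must equal seq_length", call. = FALSE)
      }
      n <- length(gene_tree$tip.label)
      root <- n + 1L
      kids <- tree_children(gene_tree)
      elen <- numeric(n + gene_tree$Nnode)
      elen[gene_tree$edge[, 2]] <- gene_tree$edge.length
      evolve <- function(seq_chars, t) {
        # exact 20-state equal-rates transition over a branch of length t
        # (subst_rate = expected substitutions per site per unit length):
        # P(site ends in a different residue) = (19/20)(1 - exp(-(20/19) r t)),
        # uniformly spread over the 19 alternatives.  Multiple jumps within
        # one branch, including returns to the original residue, are thereby
        # accounted for, so pairwise identities follow the 20-state
        # Jukes-Cantor-type closed form along any path.
        p_change <- (19 / 20) * (1 - exp(-(20 / 19) * config$subst_rate * t))
        hit <- stats::runif(length(seq_chars)) < p_change
        if (any(hit)) {
          seq_chars[hit] <- vapply(seq_chars[hit], function(old) {
            sample(setdiff(AA20, old), 1L)
          }, "")
        }
        seq_chars
      }
      walk <- function(node, seq_chars) {
        seq_chars <- evolve(seq_chars, elen[[node]])
        if (node <= n) {
          name <- gene_tree$tip.label[[node]]
          sp <- sub("__[0-9]+$", "", name)
          proteomes[[sp]][[length(proteomes[[sp]]) + 1L]] <<-
            seq_record(name, paste(seq_chars, collapse = ""), species = sp)
        } else {
          for (ch in kids[[node]]) walk(ch, seq_chars)
        }
        invisible(NULL)
      }
      root_chars <- strsplit(root_seq, "")[[1]]
      # the root itself carries no branch
      for (ch in kids[[root]]) walk(ch, root_chars)
    }
    for (sp in species) {
      for (k in seq_len(config$n_decoys_per_species)) {
        len <- sample(200:800, 1L)
        proteomes[[sp]][[length(proteomes[[sp]]) + 1L]] <-
          seq_record(sprintf("decoy_%s_%d", sp, k), random_sequence(len),
                     species = sp)
      }
    }
    proteomes
  })
}

#' Describe a true consumption curve
#'
#' @param substrate substrate name.
#' @param c0 starting concentration, g/L (> 0).
#' @param true_rate consumption rate, g/L/h (>= 0).
#' @param times sampling times in hours, strictly increasing.
#' @param noise_sd Gaussian noise standard deviation, g/L (>= 0).
#' @param breakpoint optional time of a rate change, hours.
#' @param rate_after rate after the breakpoint, g/L/h.
#' @param strain strain name.
#' @return a list of class `consumption_truth`.
#' @export
consumption_truth <- function(substrate, c0, true_rate, times,
                              noise_sd = 0, breakpoint = NULL,
                              rate_after = NULL, strain = "strain") {
  stopifnot(c0 > 0, true_rate >= 0, length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (noise_sd < 0) stop("negative noise_sd", call. = FALSE)
  if (!is.null(breakpoint) && is.null(rate_after)) {
    stop("breakpoint requires rate_after", call. = FALSE)
  }
  structure(list(substrate = substrate, c0 = c0, true_rate = true_rate,
                 times = as.numeric(times), noise_sd = noise_sd,
                 breakpoint = breakpoint, rate_after = rate_after,
                 strain = strain),
            class = "consumption_truth")
}

#' Simulate a noisy consumption time series
#'
#' The noiseless curve is `max(0, c0 - rate * t)` up to the optional
#' breakpoint and continues from the breakpoint concentration at
#' `rate_after` beyond it; Gaussian noise of sd `noise_sd` is added and the
#' result re-clipped at zero.
#'
#' @param truth a [consumption_truth()].
#' @param seed integer seed.
#' @return a [time_series()].
#' @export
simulate_consumption_series <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "consumption_truth"))
  t <- truth$times
  clean <- if (is.null(truth$breakpoint)) {
    pmax(0, truth$c0 - truth$true_rate * t)
  } else {
    cb <- max(0, truth$c0 - truth$true_rate * truth$breakpoint)
    ifelse(t < truth$breakpoint,
           pmax(0, truth$c0 - truth$true_rate * t),
           pmax(0, cb - truth$rate_after * (t - truth$breakpoint)))
  }
  noisy <- with_seed(seed, {
    pmax(0, clean + stats::rnorm(length(t), sd = truth$noise_sd))
  })
  time_series(t, noisy, substrate = truth$substrate, strain = truth$strain)
}
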