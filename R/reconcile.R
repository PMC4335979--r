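# Basic rooted-tree helpers on ape phylo objects -----------------------------

tree_parents <- function(tree) {
  n <- length(tree$tip.label)
  par <- integer(n + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par  # 0 for the root
}

tree_children <- function(tree) {
  n <- length(tree$tip.label)
  kids <- vector("list", n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  kids
}

tree_depths <- function(tree) {
  n <- length(tree$tip.label)
  par <- tree_parents(tree)
  depth <- integer(n + tree$Nnode)
  ord <- rev(ape::postorder(tree))  # edges, root-most first
  for (e in ord) {
    child <- tree$edge[e, 2]
    depth[child] <- depth[tree$edge[e, 1]] + 1L
  }
  depth
}

is_binary_rooted <- function(tree) {
  deg <- table(factor(tree$edge[, 1],
                      levels = seq_len(length(tree$tip.label) + tree$Nnode)))
  internal <- deg[deg > 0]
  all(internal == 2L)
}

node_name <- function(tree, id) {
  n <- length(tree$tip.label)
  if (id <= n) return(tree$tip.label[[id]])
  lab <- if (!is.null(tree$node.label)) tree$node.label[[id - n]] else ""
  if (is.na(lab) || !nzchar(lab)) sprintf("node%d", id) else lab
}

#' Derive a gene-to-species leaf map from gene names
#'
#' Gene leaves named `species__k` (the simulator's convention) are mapped to
#' their species token.
#'
#' @param gene_leaves character vector of gene leaf names.
#' @return named character vector: gene leaf -> species leaf.
#' @export
leaf_map_from_names <- function(gene_leaves) {
  stats::setNames(sub("__[0-9]+$", "", gene_leaves), gene_leaves)
}

#' Duplication-loss parsimony reconciliation
#'
#' Embeds a rooted binary gene tree into a rooted binary species tree by the
#' LCA mapping: each gene node maps to the lowest common ancestor of its
#' children's images.  A gene node is a duplication when its image equals a
#' child's image; otherwise it is a speciation.  Losses are charged for the
#' species branches skipped between a node's image and a child's image
#' (path length minus one for speciations, path length for duplications),
#' and placed on the sibling branches passed over.  The resulting
#' duplication and loss counts are the minimum over all reconciliations of
#' the given rooted trees.
#'
#' @param gene_tree rooted binary [ape::phylo] gene tree.
#' @param species_tree rooted binary [ape::phylo] species tree.
#' @param leaf_map named character vector mapping every gene leaf to a
#'   species leaf; by default derived from `species__k` gene names.
#' @return an object of class `reconciliation`: list with `mapping` (gene
#'   node id -> species node id), `events` (per internal gene node,
#'   `"speciation"` or `"duplication"`), `losses` (data frame `gene_child`,
#'   `species_branch` naming the species node whose stem carries the loss),
#'   `n_duplications`, `n_losses`, and the input trees.
#' @export
lca_reconcile <- function(gene_tree, species_tree,
                          leaf_map = leaf_map_from_names(gene_tree$tip.label)) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!is_binary_rooted(gene_tree) || !ape::is.rooted(gene_tree)) {
    stop("gene tree must be rooted and binary", call. = FALSE)
  }
  if (!is_binary_rooted(species_tree) || !ape::is.rooted(species_tree)) {
    stop("species tree must be rooted and binary", call. = FALSE)
  }
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_map))
  if (length(unmapped) > 0L) {
    stop(sprintf("unmapped gene leaf(s): %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(leaf_map[gene_tree$tip.label], species_tree$tip.label)
  if (length(bad) > 0L) {
    stop(sprintf("leaf map points to unknown species: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }

  ng <- length(gene_tree$tip.label)
  sp_par <- tree_parents(species_tree)
  sp_depth <- tree_depths(species_tree)
  sp_kids <- tree_children(species_tree)
  lca <- function(a, b) {
    while (a != b) {
      if (sp_depth[a] >= sp_depth[b]) a <- sp_par[a] else b <- sp_par[b]
    }
    a
  }

  M <- integer(ng + gene_tree$Nnode)
  M[seq_len(ng)] <- match(leaf_map[gene_tree$tip.label],
                          species_tree$tip.label)
  g_kids <- tree_children(gene_tree)
  # resolve internal images bottom-up (deepest internal nodes first)
  internal <- ng + seq_len(gene_tree$Nnode)
  for (v in rev(internal[order(tree_depths(gene_tree)[internal])])) {
    kk <- g_kids[[v]]
    M[v] <- lca(M[kk[1]], M[kk[2]])
  }

  events <- stats::setNames(character(gene_tree$Nnode), internal)
  losses <- list()
  for (v in internal) {
    kk <- g_kids[[v]]
    dup <- M[v] == M[kk[1]] || M[v] == M[kk[2]]
    events[[as.character(v)]] <- if (dup) "duplication" else "speciation"
  }
  g_par <- tree_parents(gene_tree)
  for (c_node in seq_len(ng + gene_tree$Nnode)) {
    v <- g_par[c_node]
    if (v == 0L) next
    # species path from M(c) up to M(v)
    path <- M[c_node]
    while (path[[1]] != M[v]) path <- c(sp_par[path[[1]]], path)
    k <- length(path) - 1L
    dup <- events[[as.character(v)]] == "duplication"
    start_t <- if (dup) 1L else 2L
    if (k >= start_t) {
      for (t in seq(start_t, k)) {
        # lineage passes species node path[t] heading to path[t + 1];
        # the co-lineage into the sibling branch is lost
        sib <- setdiff(sp_kids[[path[t]]], path[t + 1L])
        losses[[length(losses) + 1L]] <- data.frame(
          gene_child = node_name(gene_tree, c_node),
          species_branch = node_name(species_tree, sib),
          species_branch_id = sib,
          stringsAsFactors = FALSE)
      }
    }
  }
  loss_df <- if (length(losses)) do.call(rbind, losses) else
    data.frame(gene_child = character(), species_branch = character(),
               species_branch_id = integer(), stringsAsFactors = FALSE)
  structure(list(
    mapping = M,
    events = events,
    losses = loss_df,
    n_duplications = sum(events == "duplication"),
    n_losses = nrow(loss_df),
    gene_tree = gene_tree,
    species_tree = species_tree),
    class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation> %d duplications, %d losses\n",
              x$n_duplications, x$n_losses))
  invisible(x)
}

# Resolve a species clade given a node name or a set of tip labels (MRCA).
resolve_species_node <- function(species_tree, species_clade) {
  n <- length(species_tree$tip.label)
  if (length(species_clade) == 1L) {
    all_names <- vapply(seq_len(n + species_tree$Nnode),
                        function(i) node_name(species_tree, i), "")
    id <- match(species_clade, all_names)
    if (is.na(id)) stop(sprintf("unknown species clade '%s'", species_clade),
                        call. = FALSE)
    return(id)
  }
  missing <- setdiff(species_clade, species_tree$tip.label)
  if (length(missing) > 0L) {
    stop(sprintf("unknown species tip(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ape::getMRCA(species_tree, species_clade)
}

clade_node_ids <- function(species_tree, root_id) {
  kids <- tree_children(species_tree)
  out <- integer()
  stack <- root_id
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  out
}

#' Annotate a gene tree with reconciliation events
#'
#' @param result a [lca_reconcile()] result.
#' @return the gene tree with internal node labels `"D"` (duplication) or
#'   `"S"` (speciation), ready for [write_newick()].
#' @export
annotate_events <- function(result) {
  stopifnot(inherits(result, "reconciliation"))
  gt <- result$gene_tree
  n <- length(gt$tip.label)
  gt$node.label <- ifelse(
    result$events[as.character(n + seq_len(gt$Nnode))] == "duplication",
    "D", "S")
  gt
}

#' Validate user-asserted ortholog pairs against a reconciliation
#'
#' External evidence (for example conserved synteny) sometimes asserts that
#' two genes are orthologs.  Under a reconciliation, a gene pair is
#' orthologous exactly when their gene-tree LCA is a speciation node.  Each
#' asserted pair is checked; violations are reported with a warning.
#'
#' @param result a [lca_reconcile()] result.
#' @param pairs two-column character matrix or data frame of gene leaf
#'   names asserted to be orthologs.
#' @return logical vector, one element per pair: TRUE when the pair is
#'   orthologous under the reconciliation.
#' @export
check_ortholog_constraints <- function(result, pairs) {
  stopifnot(inherits(result, "reconciliation"))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  gt <- result$gene_tree
  missing <- setdiff(as.vector(pairs), gt$tip.label)
  if (length(missing) > 0L) {
    stop(sprintf("unknown gene leaf(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    anc <- ape::getMRCA(gt, pairs[i, ])
    result$events[[as.character(anc)]] == "speciation"
  }, TRUE)
  if (any(!ok)) {
    bad <- pairs[!ok, , drop = FALSE]
    warning(sprintf(
      "asserted ortholog pair(s) violate the reconciliation: %s",
      paste(apply(bad, 1L, paste, collapse = "/"), collapse = ", ")))
  }
  ok
}

#' Count reconciliation events within a species clade
#'
#' Restricts the duplication and loss counts of a reconciliation to the
#' branches of one species clade, including the clade's stem branch.
#'
#' @param result a [lca_reconcile()] result.
#' @param species_clade a species node name, or a character vector of
#'   species tips whose MRCA defines the clade.
#' @return named numeric vector `c(duplications=, losses=, total=)`.
#' @export
clade_event_summary <- function(result, species_clade) {
  stopifnot(inherits(result, "reconciliation"))
  sp <- result$species_tree
  root_id <- resolve_species_node(sp, species_clade)
  ids <- clade_node_ids(sp, root_id)
  dups <- sum(result$events == "duplication" &
                result$mapping[as.integer(names(result$events))] %in% ids)
  losses <- sum(result$losses$species_branch_id %in% ids)
  c(duplications = dups, losses = losses, total = dups + losses)
}

#' Per-branch event and copy-number report
#'
#' One row per species-tree branch (identified by the node below it; the
#' root row describes the stem) giving the duplications and losses placed on
#' the branch and the gene-copy counts entering and leaving it.  The copies
#' leaving are counted independently from the reconciliation's edge paths,
#' so the bookkeeping identity
#' `leaving = entering + duplications - losses` is a genuine consistency
#' check of the event placements.
#'
#' @param result a [lca_reconcile()] result.
#' @return data frame with columns `branch`, `entering`, `duplications`,
#'   `losses`, `leaving`.
#' @export
scenario_report <- function(result) {
  stopifnot(inherits(result, "reconciliation"))
  sp <- result$species_tree
  gt <- result$gene_tree
  n_sp <- length(sp$tip.label)
  n_nodes <- n_sp + sp$Nnode
  sp_par <- tree_parents(sp)
  root_id <- which(sp_par == 0L)
  M <- result$mapping
  ng <- length(gt$tip.label)
  g_par <- tree_parents(gt)
  g_root <- which(g_par == 0L)
  is_dup <- function(v) {
    v > ng && result$events[[as.character(v)]] == "duplication"
  }

  dup_at <- tabulate(M[as.integer(names(result$events))[
    result$events == "duplication"]], nbins = n_nodes)
  loss_at <- tabulate(result$losses$species_branch_id, nbins = n_nodes)

  # independent count of lineages arriving at each species node, from the
  # species path covered by each gene edge
  arriving <- integer(n_nodes)
  if (!is_dup(g_root)) arriving[M[g_root]] <- arriving[M[g_root]] + 1L
  for (c_node in seq_len(ng + gt$Nnode)) {
    v <- g_par[c_node]
    if (v == 0L) next
    path <- M[c_node]
    while (path[[1]] != M[v]) path <- c(sp_par[path[[1]]], path)
    covered <- if (is_dup(v)) path else path[-1L]
    if (is_dup(c_node)) covered <- setdiff(covered, M[c_node])
    for (s in covered) arriving[s] <- arriving[s] + 1L
  }

  # the reconciled family enters the species tree on the stem of the gene
  # root's image; branches above it carry no copies
  origin <- M[g_root]
  rows <- lapply(seq_len(n_nodes), function(s) {
    entering <- if (s == origin) 1L else if (s == root_id) 0L else
      arriving[sp_par[s]]
    data.frame(branch = node_name(sp, s),
               entering = entering,
               duplications = dup_at[s],
               losses = loss_at[s],
               leaving = arriving[s],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
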