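# Independent oracles used across the test files.  These deliberately avoid
# the package's own DP/agglomeration code paths.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) paste(sample(aa20, len, replace = TRUE),
                                      collapse = "")

# ---- alignment oracle: plain recursion, no memoisation ---------------------

# Maximum global alignment score of a[i..], b[j..] given the previous column
# type (0 = start/match, 1 = gap in a, 2 = gap in b).  Affine cost
# go + (L-1)*ge.  Exponential; only for short sequences.
brute_global_score <- function(a, b, scheme) {
  sub <- scheme$full
  go <- scheme$gap_open; ge <- scheme$gap_extend
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(va) && j > length(vb)) return(0)
    best <- -Inf
    if (i <= length(va) && j <= length(vb)) {
      best <- max(best, sub[va[i], vb[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (j <= length(vb)) {  # gap in a
      cost <- if (prev == 1L) ge else go
      best <- max(best, -cost + rec(i, j + 1L, 1L))
    }
    if (i <= length(va)) {  # gap in b
      cost <- if (prev == 2L) ge else go
      best <- max(best, -cost + rec(i + 1L, j, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Local score: best global score over all substring pairs, floored at 0.
brute_local_score <- function(a, b, scheme) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      best <- max(best, brute_global_score(substr(a, i1, i2),
                                           substr(b, j1, j2), scheme))
    }
  }
  best
}

# ---- reconciliation oracle: DP over all valid mappings ---------------------

# Minimum total events (duplications + losses) and minimum duplication count
# over every reconciliation map of the rooted gene tree into the rooted
# species tree.  Independent formulation: gamma(v) ranges over all ancestors
# of the LCA of v's leaf species; a node is a speciation only if mapped
# exactly at the LCA of its children's images with both images in distinct
# subtrees.
recon_oracle <- function(gene_tree, species_tree, leaf_map) {
  sp_n <- length(species_tree$tip.label)
  sp_par <- integer(sp_n + species_tree$Nnode)
  sp_par[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  depth <- function(x) {
    d <- 0L
    while (sp_par[x] != 0L) { x <- sp_par[x]; d <- d + 1L }
    d
  }
  sp_depth <- vapply(seq_len(sp_n + species_tree$Nnode), depth, 0L)
  lca2 <- function(a, b) {
    while (a != b) if (sp_depth[a] >= sp_depth[b]) a <- sp_par[a] else b <- sp_par[b]
    a
  }
  ancestors <- function(x) {
    out <- x
    while (sp_par[x] != 0L) { x <- sp_par[x]; out <- c(out, x) }
    out
  }
  is_anc <- function(a, d) a %in% ancestors(d)  # a ancestor-or-equal of d
  dist_nodes <- function(a, d) sp_depth[d] - sp_depth[a]

  g_n <- length(gene_tree$tip.label)
  g_kids <- vector("list", g_n + gene_tree$Nnode)
  for (e in seq_len(nrow(gene_tree$edge))) {
    p <- gene_tree$edge[e, 1]
    g_kids[[p]] <- c(g_kids[[p]], gene_tree$edge[e, 2])
  }
  # candidate images and cost tables, bottom-up
  solve_node <- function(v) {
    if (v <= g_n) {
      s <- match(leaf_map[[gene_tree$tip.label[v]]], species_tree$tip.label)
      return(list(cands = s,
                  total = stats::setNames(0, s),
                  dups = stats::setNames(0, s)))
    }
    L <- solve_node(g_kids[[v]][1]); R <- solve_node(g_kids[[v]][2])
    # candidate images: every ancestor-or-equal of the LCA of v's leaf
    # species (the lowest candidate of each child chain is its own LCA)
    cands <- ancestors(lca2(L$cands[1], R$cands[1]))
    total <- dups <- stats::setNames(rep(Inf, length(cands)),
                                     cands)
    for (s in cands) {
      for (sl in L$cands) {
        if (!is_anc(s, sl)) next
        for (sr in R$cands) {
          if (!is_anc(s, sr)) next
          l <- lca2(sl, sr)
          spec <- (s == l) && (s != sl) && (s != sr)
          ev_total <- if (spec) {
            (dist_nodes(s, sl) - 1) + (dist_nodes(s, sr) - 1)
          } else {
            1 + dist_nodes(s, sl) + dist_nodes(s, sr)
          }
          ev_dup <- if (spec) 0 else 1
          key <- as.character(s)
          cand_total <- L$total[[as.character(sl)]] +
            R$total[[as.character(sr)]] + ev_total
          cand_dups <- L$dups[[as.character(sl)]] +
            R$dups[[as.character(sr)]] + ev_dup
          if (cand_total < total[[key]]) total[[key]] <- cand_total
          if (cand_dups < dups[[key]]) dups[[key]] <- cand_dups
        }
      }
    }
    keep <- is.finite(total)
    list(cands = as.integer(names(total))[keep],
         total = total[keep], dups = dups[keep])
  }
  root <- g_n + 1L
  res <- solve_node(root)
  list(min_total = min(res$total), min_duplications = min(res$dups))
}

# ---- tree generators -------------------------------------------------------

# random rooted binary tree with positive branch lengths, leaves t1..tn
random_binary_tree <- function(n, min_len = 0.1, max_len = 1) {
  tr <- ape::rtree(n, rooted = TRUE, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# additive distance matrix of a tree, via the independent ape implementation
additive_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  distance_matrix(d)
}

# ---- motif oracle ----------------------------------------------------------

pattern_to_regex <- function(pattern) {
  paste(vapply(pattern$elements, function(e) {
    switch(e$type,
           any = ".",
           fixed = e$residues,
           class = paste0("[", paste(e$residues, collapse = ""), "]"))
  }, ""), collapse = "")
}

regex_scan_starts <- function(residues, pattern) {
  rx <- sprintf("(?=(%s))", pattern_to_regex(pattern))
  m <- gregexpr(rx, residues, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}
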