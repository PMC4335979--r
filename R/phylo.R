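#' Construct a distance matrix object
#'
#' @param d symmetric numeric matrix with zero diagonal, non-negative finite
#'   entries, and identical row/column names (the taxon labels).
#' @return an object of class `distance_matrix`.
#' @export
distance_matrix <- function(d) {
  if (!is.matrix(d) || is.null(rownames(d)) ||
      !identical(rownames(d), colnames(d))) {
    stop("'d' must be a square matrix with matching row/column names",
         call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(list(labels = rownames(d), d = d), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d taxa\n", length(x$labels)))
  print(round(x$d, 4))
  invisible(x)
}

#' Pairwise p-distances from a multiple alignment
#'
#' For each pair of rows, the fraction of mismatching residues over the
#' columns where both rows carry a residue (pairwise deletion of gap
#' columns).
#'
#' @param msa a [multiple_alignment()] with at least 2 rows.
#' @return a [distance_matrix()] of p-distances.
#' @export
p_distance_matrix <- function(msa) {
  stopifnot(inherits(msa, "multiple_alignment"))
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  res <- mat != "-"
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- res[i, ] & res[j, ]
      nc <- sum(both)
      if (nc == 0L) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     msa$ids[[i]], msa$ids[[j]]), call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(mat[i, both] != mat[j, both]) / nc
    }
  }
  distance_matrix(d)
}

#' Correct observed p-distances for multiple substitutions
#'
#' `model = "poisson"`: `d = -ln(1 - p)`.  `model = "gamma"`: rate
#' heterogeneity across sites with shape `alpha`,
#' `d = alpha * ((1 - p)^(-1/alpha) - 1)`; as `alpha` grows this converges
#' to the Poisson correction.  Distances with `p > 0.99` are treated as
#' saturated: an error by default, or capped at `max_distance` when
#' `saturation = "cap"`.
#'
#' @param p observed proportion(s) of differing sites, in `[0, 1)`.
#' @param model `"poisson"` or `"gamma"`.
#' @param alpha gamma shape parameter (> 0), used when `model = "gamma"`.
#' @param saturation `"error"` (default) or `"cap"`.
#' @param max_distance cap applied to saturated distances (default 10).
#' @return corrected distance(s), substitutions per site.
#' @export
correct_distance <- function(p, model = c("poisson", "gamma"), alpha = 1.0,
                             saturation = c("error", "cap"),
                             max_distance = 10) {
  model <- match.arg(model)
  saturation <- match.arg(saturation)
  if (any(p < 0) || any(p >= 1)) {
    stop("p must lie in [0, 1); p >= 1 is saturated", call. = FALSE)
  }
  sat <- p > 0.99
  if (any(sat) && saturation == "error") {
    stop("saturated distance(s): p > 0.99; use saturation = \"cap\"",
         call. = FALSE)
  }
  d <- if (model == "poisson") {
    -log(1 - p)
  } else {
    if (!(alpha > 0) || !is.finite(alpha)) stop("alpha must be positive and finite",
                                                call. = FALSE)
    alpha * ((1 - p)^(-1 / alpha) - 1)
  }
  d[sat] <- pmin(d[sat], max_distance)
  d
}

#' Apply a distance correction to a whole matrix
#'
#' @param D a [distance_matrix()] of p-distances.
#' @param ... passed to [correct_distance()].
#' @return a corrected [distance_matrix()].
#' @export
correct_distance_matrix <- function(D, ...) {
  stopifnot(inherits(D, "distance_matrix"))
  m <- D$d
  off <- upper.tri(m) | lower.tri(m)
  m[off] <- correct_distance(m[off], ...)
  distance_matrix(m)
}

# Shared agglomeration loop for NJ and BioNJ.  Nodes carry a representative
# label (the lexicographically smallest leaf beneath them) used only for
# deterministic tie-breaking in the Q search.
nj_engine <- function(D, bionj = FALSE, V = NULL) {
  stopifnot(inherits(D, "distance_matrix"))
  d <- D$d
  labels <- D$labels
  n <- length(labels)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    return(read_newick(sprintf("(%s:%.17g,%s:%.17g);",
                               labels[1], d[1, 2] / 2,
                               labels[2], d[1, 2] / 2)))
  }
  if (bionj) {
    v <- if (is.null(V)) d else V
  }
  newick <- labels          # growing newick fragment per active node
  reps <- labels            # representative label per active node
  repeat {
    r <- nrow(d)
    if (r == 3L) break
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(reps[ij[1]], reps[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(pair_keys)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    k <- setdiff(seq_len(r), c(i, j))
    if (bionj) {
      vij <- v[i, j]
      lam <- if (vij > 0) {
        0.5 + sum(v[j, k] - v[i, k]) / (2 * (r - 2) * vij)
      } else 0.5
      lam <- min(1, max(0, lam))
      dnew <- lam * (d[i, k] - bi) + (1 - lam) * (d[j, k] - bj)
      vnew <- lam * v[i, k] + (1 - lam) * v[j, k] - lam * (1 - lam) * vij
    } else {
      dnew <- (d[i, k] + d[j, k] - d[i, j]) / 2
    }
    frag <- sprintf("(%s:%.17g,%s:%.17g)", newick[i], bi, newick[j], bj)
    rep_new <- min(reps[i], reps[j])
    d <- d[k, k, drop = FALSE]
    d <- rbind(cbind(d, dnew), c(dnew, 0))
    if (bionj) {
      v <- v[k, k, drop = FALSE]
      v <- rbind(cbind(v, pmax(vnew, 0)), c(pmax(vnew, 0), 0))
    }
    newick <- c(newick[k], frag)
    reps <- c(reps[k], rep_new)
  }
  # join the last three nodes on a central vertex
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  bl <- c(b1, b2, b3)
  for (idx in which(bl < 0)) {
    others <- setdiff(1:3, idx)
    bl[others] <- bl[others] + bl[idx] / 2
    bl[idx] <- 0
  }
  txt <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 newick[1], bl[1], newick[2], bl[2], newick[3], bl[3])
  read_newick(txt)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimising
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j`, with branch lengths from the
#' three-point formulas.  Ties are broken by the lexicographically smallest
#' pair of representative labels, and negative branch lengths are clamped to
#' zero with the deficit moved to the sibling edge, so output is
#' deterministic and non-negative.
#'
#' @param D a [distance_matrix()].
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) nj_engine(D, bionj = FALSE)

#' BioNJ tree from a distance matrix
#'
#' Neighbor-Joining with BioNJ's variance-weighted reduction: when nodes i
#' and j are joined, the new distances are a convex combination with weight
#' `lambda` chosen to minimise the variance of the reduced distance
#' estimates (clamped to `[0, 1]`), and variances are reduced alongside.
#' The default variance matrix is the distance matrix itself.
#'
#' @param D a [distance_matrix()].
#' @param V optional variance matrix (defaults to `D`).
#' @return an unrooted [ape::phylo] tree.
#' @export
bionj <- function(D, V = NULL) {
  if (!is.null(V)) {
    if (inherits(V, "distance_matrix")) V <- V$d
    stopifnot(identical(dim(V), dim(D$d)))
  }
  nj_engine(D, bionj = TRUE, V = V)
}

# Non-trivial bipartition keys of an unrooted tree: for each internal edge,
# the leaf set below it, normalised so the side not containing the
# alphabetically first leaf is the key.
bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  all_leaves <- sort(tree$tip.label)
  ref <- all_leaves[[1]]
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[[i]]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; c <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  keys <- character()
  for (e in seq_len(nrow(tree$edge))) {
    side <- below[[tree$edge[e, 2]]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (ref %in% side) side <- setdiff(all_leaves, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference between the trees' sets of non-trivial
#' bipartitions.  Both trees must share the same leaf set; rootings are
#' ignored.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaves.
#' @return a non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  k1 <- bipartition_keys(t1)
  k2 <- bipartition_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Root a tree with an outgroup
#'
#' Places the root at the midpoint of the edge separating the outgroup
#' leaves from the rest.  The outgroup must be monophyletic in the unrooted
#' sense; internal labels (bootstrap supports) are carried over.
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup a leaf name or character vector of leaf names.
#' @return a rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing) > 0L) {
    stop(sprintf("outgroup leaf(s) not in tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- length(tree$tip.label)
  if (length(outgroup) > 1L && length(outgroup) < n - 1L) {
    key <- paste(sort(as.character(outgroup)), collapse = "\r")
    ref <- sort(tree$tip.label)[[1]]
    side <- if (ref %in% outgroup) {
      paste(sort(setdiff(tree$tip.label, outgroup)), collapse = "\r")
    } else key
    if (!(side %in% bipartition_keys(tree))) {
      stop("outgroup is not monophyletic", call. = FALSE)
    }
  }
  rooted <- ape::root(ape::unroot(tree), outgroup = outgroup,
                      resolve.root = TRUE, edgelabel = TRUE)
  root_node <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1] == root_node)
  if (length(re) == 2L && !is.null(rooted$edge.length)) {
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- tot / 2
  }
  rooted
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with the chosen builder on (optionally corrected) p-distances,
#' and reports for each internal bipartition of the main tree the percentage
#' of replicates containing it.  Replicates whose distance computation fails
#' (for example a pair with no comparable columns, or a saturated distance)
#' are skipped with a warning and counted.
#'
#' @param msa a [multiple_alignment()].
#' @param builder `"nj"` or `"bionj"`, or a function mapping a
#'   [distance_matrix()] to a tree.
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed integer seed controlling the resampling.
#' @param correction `"p"` (no correction), `"poisson"`, or `"gamma"`.
#' @param alpha gamma shape parameter when `correction = "gamma"`.
#' @return list of class `bootstrap_result`: `main_tree` (with supports as
#'   internal node labels), `supports` (named vector, percent),
#'   `n_replicates`, `n_skipped`.
#' @export
bootstrap_support <- function(msa, builder = c("nj", "bionj"),
                              n_replicates = 100L, seed = 1L,
                              correction = c("p", "poisson", "gamma"),
                              alpha = 1.0) {
  stopifnot(inherits(msa, "multiple_alignment"), n_replicates >= 1L)
  correction <- match.arg(correction)
  build <- if (is.function(builder)) builder else {
    switch(match.arg(builder), nj = neighbor_joining, bionj = bionj)
  }
  dist_fun <- function(m) {
    D <- p_distance_matrix(m)
    if (correction != "p") {
      D <- correct_distance_matrix(D, model = correction, alpha = alpha)
    }
    D
  }
  main <- build(dist_fun(msa))
  main_keys <- bipartition_keys(main)
  counts <- stats::setNames(numeric(length(main_keys)), main_keys)
  n_skipped <- 0L
  mat <- msa_matrix(msa)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(msa$n_columns, msa$n_columns, replace = TRUE)
      rep_msa <- multiple_alignment(
        msa$ids, apply(mat[, cols, drop = FALSE], 1L, paste, collapse = ""))
      tr <- tryCatch(build(dist_fun(rep_msa)), error = function(e) NULL)
      if (is.null(tr)) {
        n_skipped <- n_skipped + 1L
        next
      }
      hit <- main_keys %in% bipartition_keys(tr)
      counts[hit] <- counts[hit] + 1
    }
  })
  used <- n_replicates - n_skipped
  if (n_skipped > 0L) {
    warning(sprintf("%d bootstrap replicate(s) skipped", n_skipped))
  }
  supports <- if (used > 0) 100 * counts / used else counts * NA_real_
  # attach supports to the main tree's internal nodes
  n <- length(main$tip.label)
  node_lab <- rep("", main$Nnode)
  post <- ape::reorder.phylo(main, "postorder")
  below <- vector("list", n + main$Nnode)
  for (i in seq_len(n)) below[[i]] <- main$tip.label[[i]]
  for (e in seq_len(nrow(post$edge))) {
    below[[post$edge[e, 1]]] <- c(below[[post$edge[e, 1]]],
                                  below[[post$edge[e, 2]]])
  }
  all_leaves <- sort(main$tip.label)
  ref <- all_leaves[[1]]
  for (v in seq_len(main$Nnode)) {
    side <- below[[n + v]]
    if (length(side) < 2L || length(side) > n - 2L) {
      node_lab[[v]] <- "100"   # trivial bipartitions: 100 by convention
      next
    }
    if (ref %in% side) side <- setdiff(all_leaves, side)
    key <- paste(sort(side), collapse = "\r")
    if (key %in% names(supports)) {
      node_lab[[v]] <- sprintf("%g", round(supports[[key]], 1))
    }
  }
  main$node.label <- node_lab
  structure(list(main_tree = main, supports = supports,
                 n_replicates = n_replicates, n_skipped = n_skipped),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates (%d skipped)\n",
              x$n_replicates, x$n_skipped))
  if (length(x$supports)) {
    cat("  supports:", paste(round(unname(x$supports), 1), collapse = ", "),
        "\n")
  }
  invisible(x)
}
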