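#' Construct a multiple alignment object
#'
#' @param ids character vector of row ids (unique).
#' @param rows character vector of equal-length aligned strings (gaps `-`).
#' @return an object of class `multiple_alignment` with fields `ids`, `rows`,
#'   `n_columns`.
#' @export
multiple_alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), !anyDuplicated(ids))
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 n_columns = if (length(rows)) widths[[1]] else 0L),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d sequences x %d columns\n",
              length(x$rows), x$n_columns))
  w <- max(nchar(x$ids))
  for (i in seq_along(x$rows)) {
    row <- x$rows[[i]]
    if (nchar(row) > 60L) row <- paste0(substr(row, 1L, 57L), "...")
    cat(sprintf("  %-*s %s\n", w, x$ids[[i]], row))
  }
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}

# Column residue counts of an alignment block (21 x n_columns, gaps excluded).
profile_counts <- function(mat) {
  counts <- matrix(0, nrow = 21L, ncol = ncol(mat),
                   dimnames = list(AA_ALPHABET, NULL))
  for (k in seq_len(21L)) counts[k, ] <- colSums(mat == AA_ALPHABET[[k]])
  counts
}

# Align two profiles (character matrices) by profile-profile
# Needleman-Wunsch: the score of pairing two columns is the arithmetic mean
# of substitution scores over all residue-residue pairs (gap entries
# ignored); new gaps pay the scheme's affine penalties.
merge_profiles <- function(ma, mb, scheme) {
  fa <- profile_counts(ma); fb <- profile_counts(mb)
  na <- colSums(fa); nb <- colSums(fb)
  S <- crossprod(fa, scheme$full %*% fb) / outer(na, nb)
  res <- align_affine_cpp(S, scheme$gap_open, scheme$gap_extend, FALSE)
  expand <- function(mat, idx) {
    out <- matrix("-", nrow = nrow(mat), ncol = length(idx))
    out[, idx > 0L] <- mat[, idx[idx > 0L], drop = FALSE]
    out
  }
  rbind(expand(ma, res$a_idx), expand(mb, res$b_idx))
}

# Post-order list of tip-index groups giving the progressive merge order
# implied by a guide tree.
merge_order <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= n) return(node)
    parts <- lapply(kids[[as.character(node)]], rec)
    Reduce(c, parts)
  }
  plan <- list()
  walk <- function(node) {
    if (node <= n) return(node)
    parts <- lapply(kids[[as.character(node)]], walk)
    acc <- parts[[1]]
    for (k in seq_along(parts)[-1]) {
      plan[[length(plan) + 1L]] <<- list(a = acc, b = parts[[k]])
      acc <- c(acc, parts[[k]])
    }
    acc
  }
  walk(root)
  plan
}

#' Progressive multiple sequence alignment
#'
#' Standard progressive alignment: all-pairs global alignment distances
#' (`1 - identity / 100`) feed a Neighbor-Joining guide tree, and profiles
#' are merged bottom-up by profile-profile Needleman-Wunsch with column
#' scores averaged over residue pairs.  Row order in the result matches the
#' input order.  A single sequence is returned as a one-row alignment.
#'
#' @param seqs list of [seq_record()]s.
#' @param scheme a [scoring_scheme()].
#' @return a [multiple_alignment()].
#' @export
progressive_align <- function(seqs, scheme = default_scheme()) {
  ids <- vapply(seqs, `[[`, "", "id")
  if (length(seqs) == 1L) return(multiple_alignment(ids, seqs[[1]]$residues))
  if (length(seqs) == 2L) {
    aln <- global_align(seqs[[1]], seqs[[2]], scheme)
    return(multiple_alignment(ids, c(aln$aligned_a, aln$aligned_b)))
  }
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- global_align(seqs[[i]], seqs[[j]], scheme)
      D[i, j] <- D[j, i] <- 1 - identity_similarity(aln, scheme)[["identity"]] / 100
    }
  }
  guide <- neighbor_joining(distance_matrix(D))
  # guide-tree tips are ids; convert to input indices
  tip_idx <- match(guide$tip.label, ids)
  profiles <- lapply(seqs, function(s) {
    matrix(strsplit(s$residues, "")[[1]], nrow = 1L)
  })
  plan <- merge_order(guide)
  store <- list()  # current profile per sorted index-set key
  key <- function(v) paste(sort(v), collapse = ",")
  get_prof <- function(v) {
    if (length(v) == 1L) profiles[[tip_idx[v]]] else store[[key(v)]]
  }
  for (step in plan) {
    pa <- get_prof(step$a); pb <- get_prof(step$b)
    store[[key(c(step$a, step$b))]] <- merge_profiles(pa, pb, scheme)
  }
  final <- store[[key(seq_len(n))]]
  # rows of `final` follow the last merge's accumulation order (guide-tree
  # tip indices); restore the input order
  last <- plan[[length(plan)]]
  final <- final[order(tip_idx[c(last$a, last$b)]), , drop = FALSE]
  multiple_alignment(ids, apply(final, 1L, paste, collapse = ""))
}

#' Conserved-block filtering of an alignment
#'
#' Column filter in the spirit of Gblocks: a column is eligible when its gap
#' fraction is at most `max_gap_fraction` and its most frequent residue
#' (gaps excluded) accounts for at least `min_conserved_fraction` of the
#' residues; maximal runs of eligible columns shorter than
#' `min_block_length` are then dropped.
#'
#' @param msa a [multiple_alignment()].
#' @param max_gap_fraction maximum tolerated gap fraction per column.
#' @param min_conserved_fraction minimum frequency of the majority residue.
#' @param min_block_length minimum run length of eligible columns kept.
#' @return list with `msa` (the filtered [multiple_alignment()]) and
#'   `kept_columns` (1-based indices into the input columns).
#' @export
filter_blocks <- function(msa, max_gap_fraction = 0.5,
                          min_conserved_fraction = 0.5,
                          min_block_length = 3L) {
  stopifnot(inherits(msa, "multiple_alignment"),
            max_gap_fraction >= 0, max_gap_fraction <= 1,
            min_conserved_fraction >= 0, min_conserved_fraction <= 1,
            min_block_length >= 1L)
  mat <- msa_matrix(msa)
  nr <- nrow(mat)
  gapfrac <- colSums(mat == "-") / nr
  consfrac <- apply(mat, 2L, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0L) return(0)
    max(table(res)) / length(res)
  })
  eligible <- gapfrac <= max_gap_fraction & consfrac >= min_conserved_fraction
  keep <- logical(length(eligible))
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[[k]] && r$lengths[[k]] >= min_block_length) {
      keep[starts[[k]]:ends[[k]]] <- TRUE
    }
  }
  kept <- which(keep)
  out <- mat[, kept, drop = FALSE]
  multi <- multiple_alignment(msa$ids, apply(out, 1L, paste, collapse = ""))
  list(msa = multi, kept_columns = kept)
}
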