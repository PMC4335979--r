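#' Parse a Newick tree string
#'
#' Wraps [ape::read.tree()] with explicit validation: parentheses must
#' balance, the string must end in `;`, and leaf names must be unique.
#' Numeric internal-node labels in `[0, 100]` are interpreted as bootstrap
#' support values and kept in `node.label` (see [tree_supports()]).  Branch
#' lengths follow `:` as usual; quoted labels are not supported.
#'
#' @param text a Newick string, e.g. `"((a:1,b:2)95:0.5,c:3);"`.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop("'text' must be a single Newick string", call. = FALSE)
  }
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[[i]] == "(") depth <- depth + 1L
    if (chars[[i]] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("unbalanced parentheses: %d '(' left open", depth),
         call. = FALSE)
  }
  if (!endsWith(text, ";")) {
    stop(sprintf("missing terminating ';' at position %d", nchar(text) + 1L),
         call. = FALSE)
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick string", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop(sprintf("duplicate leaf name(s): %s",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")), call. = FALSE)
  }
  tr
}

#' Serialise a tree to Newick
#'
#' Inverse of [read_newick()] up to child order.  Leaf names containing
#' Newick metacharacters are rejected.
#'
#' @param tree an [ape::phylo] tree.
#' @return a single Newick string ending in `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  bad <- grepl("[(),:;]", tree$tip.label)
  if (any(bad)) {
    stop(sprintf("leaf name(s) contain Newick metacharacters: %s",
                 paste(tree$tip.label[bad], collapse = ", ")), call. = FALSE)
  }
  ape::write.tree(tree)
}

#' Extract bootstrap supports from internal-node labels
#'
#' @param tree an [ape::phylo] tree whose `node.label` may carry numeric
#'   supports in `[0, 100]`.
#' @return numeric vector of length `tree$Nnode`; `NA` where a label is
#'   absent or not a number in range.
#' @export
tree_supports <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!is.na(sup) & (sup < 0 | sup > 100)] <- NA_real_
  sup
}
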