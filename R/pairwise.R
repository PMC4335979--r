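# Encode residues as 1-based codes into AA_ALPHABET (X = 21).
encode_residues <- function(residues) {
  codes <- match(strsplit(residues, "")[[1]], AA_ALPHABET)
  if (anyNA(codes)) stop("sequence contains illegal residue characters",
                         call. = FALSE)
  codes
}

record_residues <- function(x) {
  if (inherits(x, "seq_record")) x$residues else as.character(x)
}

record_id <- function(x, default) {
  if (inherits(x, "seq_record")) x$id else default
}

new_pairwise_alignment <- function(aligned_a, aligned_b, raw_score, mode,
                                   a_span, b_span, id_a, id_b) {
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 raw_score = raw_score, mode = mode,
                 a_span = a_span, b_span = b_span,
                 id_a = id_a, id_b = id_b),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s  score %g  (%s vs %s)\n",
              x$mode, x$raw_score, x$id_a, x$id_b))
  n <- nchar(x$aligned_a)
  for (s in seq(1L, max(n, 1L), by = 60L)) {
    e <- min(s + 59L, n)
    cat(substr(x$aligned_a, s, e), "\n", substr(x$aligned_b, s, e), "\n\n",
        sep = "")
  }
  invisible(x)
}

align_pair <- function(a, b, scheme, local) {
  ra <- record_residues(a); rb <- record_residues(b)
  if (!nzchar(ra) || !nzchar(rb)) stop("cannot align an empty sequence",
                                       call. = FALSE)
  ca <- encode_residues(ra); cb <- encode_residues(rb)
  S <- scheme$full[ca, cb, drop = FALSE]
  res <- align_affine_cpp(S, scheme$gap_open, scheme$gap_extend, local)
  va <- strsplit(ra, "")[[1]]; vb <- strsplit(rb, "")[[1]]
  achr <- ifelse(res$a_idx > 0L, va[pmax(res$a_idx, 1L)], "-")
  bchr <- ifelse(res$b_idx > 0L, vb[pmax(res$b_idx, 1L)], "-")
  new_pairwise_alignment(paste(achr, collapse = ""),
                         paste(bchr, collapse = ""),
                         res$score, if (local) "local" else "global",
                         res$a_span, res$b_span,
                         record_id(a, "a"), record_id(b, "b"))
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Maximum-score global alignment under an affine gap model: a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`, and end gaps are
#' penalised.  Among co-optimal alignments the traceback deterministically
#' prefers substitution columns over gaps in the first sequence over gaps in
#' the second.
#'
#' @param a,b [seq_record()]s or plain residue strings; must be non-empty.
#' @param scheme a [scoring_scheme()]; defaults to BLOSUM62 11/1.
#' @return a `pairwise_alignment` with fields `aligned_a`, `aligned_b`
#'   (gapped strings), `raw_score`, `mode`, and the 1-based `a_span`,
#'   `b_span` covered.
#' @examples
#' aln <- global_align("HEAGAWGHEE", "PAWHEAE")
#' aln$raw_score
#' @export
global_align <- function(a, b, scheme = default_scheme()) {
  align_pair(a, b, scheme, local = FALSE)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Maximum-score local alignment under the same affine model as
#' [global_align()].  The score is always non-negative; when no residue pair
#' scores positively the alignment is empty with score 0 and zero spans.
#'
#' @inheritParams global_align
#' @return a `pairwise_alignment`.
#' @export
local_align <- function(a, b, scheme = default_scheme()) {
  align_pair(a, b, scheme, local = TRUE)
}

#' Percent identity and similarity of an alignment
#'
#' Both percentages use the full alignment length, gap columns included, as
#' the denominator (the EMBOSS convention).  A column is "similar" when its
#' substitution score is strictly positive, so similarity is always at least
#' identity.
#'
#' @param aln a `pairwise_alignment` of positive length.
#' @param scheme the [scoring_scheme()] whose matrix defines similarity.
#' @return named numeric vector `c(identity = , similarity = )`, in percent.
#' @export
identity_similarity <- function(aln, scheme = default_scheme()) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  n <- nchar(aln$aligned_a)
  if (n == 0L) stop("zero-length alignment", call. = FALSE)
  va <- strsplit(aln$aligned_a, "")[[1]]
  vb <- strsplit(aln$aligned_b, "")[[1]]
  res <- va != "-" & vb != "-"
  ident <- sum(res & va == vb & va != "X")
  sim <- 0L
  if (any(res)) {
    sim <- sum(scheme$full[cbind(match(va[res], AA_ALPHABET),
                                 match(vb[res], AA_ALPHABET))] > 0)
  }
  c(identity = 100 * ident / n, similarity = 100 * sim / n)
}
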