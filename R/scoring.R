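#' Define an affine-gap scoring scheme
#'
#' Bundles a symmetric 20x20 substitution matrix with affine gap penalties:
#' a gap of length L costs `gap_open + (L - 1) * gap_extend`.  The unknown
#' residue `X` scores 0 against everything (unknowns neither reward nor
#' penalise, and never certify similarity).
#'
#' @param matrix integer substitution matrix with the 20 canonical amino
#'   acids as row and column names.
#' @param gap_open positive gap-opening penalty (cost of a length-1 gap).
#' @param gap_extend positive per-residue extension penalty;
#'   `gap_open >= gap_extend` is required.
#' @param name token naming the scheme.
#' @return an object of class `scoring_scheme`.
#' @seealso [default_scheme()], [read_score_matrix()]
#' @export
scoring_scheme <- function(matrix, gap_open = 11, gap_extend = 1,
                           name = "custom") {
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !setequal(rownames(matrix), AA20) || !setequal(colnames(matrix), AA20)) {
    stop("'matrix' must be a 20x20 matrix named by the canonical amino acids",
         call. = FALSE)
  }
  matrix <- matrix[AA20, AA20]
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  if (!(gap_open >= gap_extend && gap_extend > 0)) {
    stop("require gap_open >= gap_extend > 0", call. = FALSE)
  }
  full <- base::matrix(0, 21L, 21L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  full[AA20, AA20] <- matrix
  structure(list(matrix = matrix, full = full,
                 gap_open = gap_open, gap_extend = gap_extend, name = name),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s  gap open %g / extend %g\n",
              x$name, x$gap_open, x$gap_extend))
  invisible(x)
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the plain-text matrix format used by NCBI BLAST (`#` comment
#' lines, a header row of residue letters, then one row per residue).
#' Letters outside the 20 canonical amino acids (B, Z, X, `*`) are dropped.
#'
#' @param path path to a matrix file.
#' @return a symmetric 20x20 integer matrix.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[[`, "", 1L)
  vals <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  dimnames(vals) <- list(labels, header)
  keep <- intersect(AA20, intersect(labels, header))
  if (length(keep) != 20L) {
    stop("matrix file does not cover the 20 canonical amino acids",
         call. = FALSE)
  }
  vals[AA20, AA20]
}

scheme_cache <- new.env(parent = emptyenv())

#' The default BLOSUM62 scheme
#'
#' BLOSUM62 with gap open 11 / extend 1 -- the standard protein search
#' defaults -- loaded from the matrix file bundled with the package.
#'
#' @return a `scoring_scheme`.
#' @export
default_scheme <- function() {
  if (is.null(scheme_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "jenscape",
                        mustWork = TRUE)
    scheme_cache$blosum62 <- scoring_scheme(read_score_matrix(path),
                                            gap_open = 11, gap_extend = 1,
                                            name = "BLOSUM62")
  }
  scheme_cache$blosum62
}

#' Karlin-Altschul parameters for E-value computation
#'
#' The defaults (`lambda = 0.267`, `K = 0.041`) are the gapped parameters
#' matching BLOSUM62 with gap open 11 / extend 1, so that E-value cutoffs
#' such as 1e-10 carry their usual meaning.
#'
#' @param m query length in residues.
#' @param n subject or database length in residues.
#' @param lambda scale parameter in nats per score unit (> 0).
#' @param K dimensionless search-space constant (> 0).
#' @return an object of class `ka_params`.
#' @export
ka_params <- function(m, n, lambda = 0.267, K = 0.041) {
  stopifnot_scalar_number(lambda, "lambda")
  stopifnot_scalar_number(K, "K")
  stopifnot_scalar_number(m, "m", min = 1)
  stopifnot_scalar_number(n, "n", min = 1)
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive", call. = FALSE)
  structure(list(lambda = lambda, K = K, m = m, n = n), class = "ka_params")
}

#' Expected number of chance hits for a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: strictly decreasing in the score and
#' linear in each of the query and database lengths.
#'
#' @param raw_score raw (not bit) alignment score.
#' @param params a [ka_params()] object.
#' @return the E-value, a non-negative number.
#' @export
evalue <- function(raw_score, params) {
  stopifnot(inherits(params, "ka_params"))
  params$K * params$m * params$n * exp(-params$lambda * raw_score)
}
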