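#' @useDynLib jenscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The 20 canonical amino acids, in the fixed order used for all scoring
# matrices and profile counts; 'X' (unknown residue) is carried as a 21st
# letter that scores 0 against everything.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA20, "X")

#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so every simulator is a pure function of its
#' arguments and seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-purpose child seed from a master seed.  Keeps results of one
# stage independent of how many draws another stage consumed.  Always below
# 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(as.integer(charToRaw(as.character(tag))) *
             seq_along(charToRaw(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("'%s' must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}
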