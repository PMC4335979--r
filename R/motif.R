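#' Parse a degenerate protein motif pattern
#'
#' Accepts the compact transporter-signature dialect: single residue
#' letters, `X`/`x` wildcards, residue classes written `(S/T)` or `[ST]`,
#' and optional `-` separators.  For example the TM7 signature of the Jen
#' carboxylate transporters, `NXX(S/T)HX(S/T)QDXXXT`, parses to 13 elements.
#'
#' @param text pattern string.
#' @return an object of class `motif_pattern`: list with `elements` (each
#'   `list(type = "fixed"|"class"|"any", residues = )`) and `source_text`.
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "")[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "-") {
      i <- i + 1L
    } else if (ch %in% c("X", "x")) {
      elements[[length(elements) + 1L]] <- list(type = "any",
                                                residues = character())
      i <- i + 1L
    } else if (ch %in% AA20 || toupper(ch) %in% AA20) {
      elements[[length(elements) + 1L]] <- list(type = "fixed",
                                                residues = toupper(ch))
      i <- i + 1L
    } else if (ch == "(" || ch == "[") {
      close_ch <- if (ch == "(") ")" else "]"
      j <- i + 1L
      members <- character()
      expect_residue <- TRUE
      while (j <= length(chars) && chars[[j]] != close_ch) {
        cj <- chars[[j]]
        if (!expect_residue && (cj == "/" || cj == ",")) {
          expect_residue <- TRUE
          j <- j + 1L
          next
        }
        if (!(toupper(cj) %in% AA20)) {
          stop(sprintf("unknown token '%s' at position %d", cj, j),
               call. = FALSE)
        }
        members <- c(members, toupper(cj))
        expect_residue <- FALSE
        j <- j + 1L
      }
      if (j > length(chars)) {
        stop(sprintf("unterminated class starting at position %d", i),
             call. = FALSE)
      }
      if (length(members) == 0L || expect_residue) {
        stop(sprintf("empty residue class at position %d", i), call. = FALSE)
      }
      elements[[length(elements) + 1L]] <- list(type = "class",
                                                residues = unique(members))
      i <- j + 1L
    } else {
      stop(sprintf("unknown token '%s' at position %d", ch, i), call. = FALSE)
    }
  }
  if (length(elements) == 0L) stop("empty pattern", call. = FALSE)
  structure(list(elements = elements, source_text = text),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  desc <- vapply(x$elements, function(e) {
    switch(e$type, any = "x", fixed = e$residues,
           class = paste0("[", paste(e$residues, collapse = ""), "]"))
  }, "")
  cat(sprintf("<motif_pattern> %s (%d elements)\n",
              paste(desc, collapse = ""), length(x$elements)))
  invisible(x)
}

pattern_length <- function(pattern) length(pattern$elements)

# TRUE where the window character satisfies the element.  An 'X' in the
# sequence (unknown residue) satisfies only wildcards: unknowns never
# certify a motif.
element_ok <- function(element, ch) {
  switch(element$type,
         any = TRUE,
         fixed = ch == element$residues,
         class = ch %in% element$residues)
}

#' Scan a sequence for motif matches
#'
#' Reports every (possibly overlapping) window in which all pattern elements
#' are satisfied, with 1-based residue coordinates and the absolute position
#' of each fixed/class anchor.
#'
#' @param seq a [seq_record()] or residue string.
#' @param pattern a [parse_pattern()] result.
#' @return data frame with columns `seq_id`, `start`, `end`, `matched`, and
#'   attribute-free anchor columns are provided via the list-column
#'   `anchors` (named integer vector per match: element index -> coordinate).
#' @export
scan_motif <- function(seq, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  residues <- record_residues(seq)
  id <- record_id(seq, "seq")
  L <- pattern_length(pattern)
  out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    matched = character(), stringsAsFactors = FALSE)
  out$anchors <- list()
  n <- nchar(residues)
  if (n < L) return(out)
  chars <- strsplit(residues, "")[[1]]
  anchor_idx <- which(vapply(pattern$elements, function(e) e$type != "any",
                             TRUE))
  rows <- list()
  for (s in seq_len(n - L + 1L)) {
    window <- chars[s:(s + L - 1L)]
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!element_ok(pattern$elements[[k]], window[[k]])) { ok <- FALSE; break }
    }
    if (ok) {
      anchors <- stats::setNames(s + anchor_idx - 1L,
                                 as.character(anchor_idx))
      rows[[length(rows) + 1L]] <- list(
        seq_id = id, start = s, end = s + L - 1L,
        matched = paste(window, collapse = ""), anchors = anchors)
    }
  }
  if (length(rows) == 0L) return(out)
  res <- data.frame(
    seq_id = vapply(rows, `[[`, "", "seq_id"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    matched = vapply(rows, `[[`, "", "matched"),
    stringsAsFactors = FALSE)
  res$anchors <- lapply(rows, `[[`, "anchors")
  res
}

#' Diagnose near-miss motif windows
#'
#' Reports windows violating at most `max_mismatches` pattern elements,
#' with each violated position's expected element and observed residue.
#' Exact matches are excluded: this is the tool for questions like "which
#' residue of the signature is replaced in this divergent paralog?".
#'
#' @param seq a [seq_record()] or residue string.
#' @param pattern a [parse_pattern()] result.
#' @param max_mismatches maximum number of violated elements (>= 1).
#' @return data frame with columns `seq_id`, `start`, `end`, `matched`,
#'   `n_mismatches`, and list-column `mismatches` (data frame per window:
#'   `element`, `expected`, `observed`).
#' @export
diagnose_motif <- function(seq, pattern, max_mismatches = 1L) {
  stopifnot(inherits(pattern, "motif_pattern"), max_mismatches >= 1L)
  residues <- record_residues(seq)
  id <- record_id(seq, "seq")
  L <- pattern_length(pattern)
  n <- nchar(residues)
  rows <- list()
  if (n >= L) {
    chars <- strsplit(residues, "")[[1]]
    for (s in seq_len(n - L + 1L)) {
      window <- chars[s:(s + L - 1L)]
      mm <- list()
      for (k in seq_len(L)) {
        el <- pattern$elements[[k]]
        if (!element_ok(el, window[[k]])) {
          mm[[length(mm) + 1L]] <- data.frame(
            element = k,
            expected = if (el$type == "fixed") el$residues else
              paste0("{", paste(el$residues, collapse = ","), "}"),
            observed = window[[k]], stringsAsFactors = FALSE)
          if (length(mm) > max_mismatches) break
        }
      }
      if (length(mm) >= 1L && length(mm) <= max_mismatches) {
        rows[[length(rows) + 1L]] <- list(
          seq_id = id, start = s, end = s + L - 1L,
          matched = paste(window, collapse = ""),
          n_mismatches = length(mm), mismatches = do.call(rbind, mm))
      }
    }
  }
  out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    matched = character(), n_mismatches = integer(),
                    stringsAsFactors = FALSE)
  out$mismatches <- list()
  if (length(rows) == 0L) return(out)
  res <- data.frame(
    seq_id = vapply(rows, `[[`, "", "seq_id"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    matched = vapply(rows, `[[`, "", "matched"),
    n_mismatches = vapply(rows, `[[`, 0L, "n_mismatches"),
    stringsAsFactors = FALSE)
  res$mismatches <- lapply(rows, `[[`, "mismatches")
  res
}
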