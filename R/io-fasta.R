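#' Construct a protein sequence record
#'
#' The basic unit handled by the pipeline: one amino-acid sequence with a
#' unique id, an optional free-text description, and the token naming the
#' source proteome.  Residues are case-normalised to upper case and must be
#' drawn from the 20 canonical amino acids plus `X` (unknown); `*` and gap
#' characters are rejected so downstream scoring stays well defined.
#'
#' @param id sequence identifier, a token without whitespace.
#' @param residues amino-acid string.
#' @param description free-text description (default `""`).
#' @param species token identifying the source proteome (default `NA`).
#' @return an object of class `seq_record`: a list with fields `id`,
#'   `description`, `residues`, `species`.
#' @examples
#' seq_record("p1", "MKVLA", species = "sp1")
#' @export
seq_record <- function(id, residues, description = "", species = NA_character_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id)) {
    stop("'id' must be a non-empty token without whitespace", call. = FALSE)
  }
  residues <- toupper(as.character(residues))
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("record '%s' contains illegal residue character(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(id = id, description = as.character(description),
                 residues = residues, species = species),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60L) res <- paste0(substr(res, 1L, 57L), "...")
  cat(sprintf("<seq_record> %s [%s] %d aa\n  %s\n",
              x$id, ifelse(is.na(x$species), "-", x$species),
              nchar(x$residues), res))
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Parses a multi-record FASTA file into a list of [seq_record()]s, attaching
#' the given species token to every record.  Wrapped sequence lines are
#' concatenated and residues upper-cased.  Windows line endings and trailing
#' whitespace are tolerated.
#'
#' @param path path to a FASTA file.
#' @param species proteome token attached to each record.
#' @return list of `seq_record` objects.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parse_fasta_lines(lines, species, path)
}

parse_fasta_lines <- function(lines, species = NA_character_, path = "<text>") {
  lines <- sub("\r$", "", lines)
  lines <- sub("[ \t]+$", "", lines)
  records <- list()
  id <- NULL; desc <- ""; chunks <- character()
  flush <- function() {
    if (is.null(id)) return()
    records[[length(records) + 1L]] <<- seq_record(
      id, paste(chunks, collapse = ""), desc, species)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      header <- sub("^>", "", line)
      id <- sub("\\s.*$", "", header)
      desc <- sub("^\\S+\\s*", "", header)
      chunks <- character()
      if (!nzchar(id)) {
        stop(sprintf("%s: empty FASTA header at line %d", path, i), call. = FALSE)
      }
    } else {
      if (is.null(id)) {
        stop(sprintf("%s: sequence data before first '>' header at line %d",
                     path, i), call. = FALSE)
      }
      chunks <- c(chunks, gsub("[ \t]", "", line))
    }
  }
  flush()
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate record id(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  records
}

#' Write records to a FASTA file
#'
#' @param records non-empty list of [seq_record()]s with unique ids.
#' @param path output path.
#' @param width line-wrap width in residues (default 60).
#' @return `path`, invisibly.  `read_fasta(write_fasta(r))` reproduces ids,
#'   descriptions and residues.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (length(records) == 0L) stop("no records to write", call. = FALSE)
  if (width < 1L) stop("'width' must be a positive integer", call. = FALSE)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  out <- character()
  for (rec in records) {
    header <- if (nzchar(rec$description)) {
      paste0(">", rec$id, " ", rec$description)
    } else paste0(">", rec$id)
    n <- nchar(rec$residues)
    starts <- seq(1L, max(n, 1L), by = width)
    body <- if (n == 0L) character() else
      substring(rec$residues, starts, pmin(starts + width - 1L, n))
    out <- c(out, header, body)
  }
  writeLines(out, path)
  invisible(path)
}
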