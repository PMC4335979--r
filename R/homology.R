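# Total residue count of a proteome (the database length n for E-values).
proteome_length <- function(proteome) {
  sum(vapply(proteome, function(r) nchar(r$residues), 0L))
}

#' Search one query against a proteome
#'
#' Locally aligns the query against every subject and converts raw scores to
#' E-values with the database length set to the proteome's total residue
#' count.  Hits with E-value above the cutoff are dropped; the rest are
#' sorted by the canonical order (E-value ascending, raw score descending,
#' subject id ascending) so "top hit" is deterministic.
#'
#' @param query a [seq_record()].
#' @param proteome non-empty list of [seq_record()]s.
#' @param scheme a [scoring_scheme()].
#' @param cutoff E-value cutoff (default `1e-10`).
#' @param lambda,K Karlin-Altschul parameters (defaults match BLOSUM62 11/1).
#' @return data frame with columns `query_id`, `subject_id`,
#'   `subject_species`, `raw_score`, `evalue`.
#' @export
search_proteome <- function(query, proteome, scheme = default_scheme(),
                            cutoff = 1e-10, lambda = 0.267, K = 0.041) {
  if (length(proteome) == 0L) stop("empty proteome", call. = FALSE)
  qc <- encode_residues(query$residues)
  subs <- lapply(proteome, function(r) encode_residues(r$residues))
  scores <- sw_scores_cpp(qc, subs, scheme$full,
                          scheme$gap_open, scheme$gap_extend)
  n_db <- proteome_length(proteome)
  ev <- vapply(scores, function(s) {
    evalue(s, ka_params(m = nchar(query$residues), n = n_db,
                        lambda = lambda, K = K))
  }, 0)
  hits <- data.frame(
    query_id = query$id,
    subject_id = vapply(proteome, `[[`, "", "id"),
    subject_species = vapply(proteome, function(r) as.character(r$species), ""),
    raw_score = as.numeric(scores),
    evalue = ev,
    stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$raw_score, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Two-step reciprocal homolog screen
#'
#' Delimits a gene family across proteomes by reciprocal best hits.  Step 1:
#' each seed protein is searched against every other species' proteome and
#' only the single top forward hit passing the E-value cutoff is considered.
#' Step 2: that hit is aligned back against the full seed proteome; it is
#' admitted to the family if and only if its top reciprocal hit is one of the
#' seed ids.  Seeds never search their own proteome.  A gene admitted via
#' several seeds is stored once, with every admitting forward/reciprocal pair
#' kept in the provenance table.
#'
#' @param seed_ids character vector of family ids within the seed proteome.
#' @param seed_proteome list of [seq_record()]s containing all `seed_ids`.
#' @param other_proteomes named list (by species token) of proteomes.
#' @param scheme a [scoring_scheme()].
#' @param cutoff forward-search E-value cutoff (default `1e-10`).
#' @return an object of class `homolog_family`: list with `seed_species`,
#'   `seed_ids`, `members` (named list species -> character vector of ids,
#'   seed species included), `provenance` and `rejects` data frames.
#' @export
reciprocal_screen <- function(seed_ids, seed_proteome, other_proteomes,
                              scheme = default_scheme(), cutoff = 1e-10) {
  seed_all_ids <- vapply(seed_proteome, `[[`, "", "id")
  missing <- setdiff(seed_ids, seed_all_ids)
  if (length(missing) > 0L) {
    stop(sprintf("seed id(s) absent from seed proteome: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(names(other_proteomes)) || any(!nzchar(names(other_proteomes)))) {
    stop("'other_proteomes' must be a named list (species tokens)",
         call. = FALSE)
  }
  seed_species <- seed_proteome[[match(seed_ids[1], seed_all_ids)]]$species
  seed_codes <- lapply(seed_proteome, function(r) encode_residues(r$residues))
  # Order-invariance: search results are sorted canonically; membership is
  # accumulated per species as a sorted id set.
  prov <- list(); rej <- list()
  members <- stats::setNames(vector("list", length(other_proteomes)),
                             names(other_proteomes))
  seeds <- seed_proteome[match(sort(seed_ids), seed_all_ids)]
  for (sp in names(other_proteomes)) {
    proteome <- other_proteomes[[sp]]
    for (seed in seeds) {
      hits <- search_proteome(seed, proteome, scheme, cutoff)
      if (nrow(hits) == 0L) next
      top <- hits[1L, ]
      cand <- proteome[[match(top$subject_id,
                              vapply(proteome, `[[`, "", "id"))]]
      back <- sw_scores_cpp(encode_residues(cand$residues), seed_codes,
                            scheme$full, scheme$gap_open, scheme$gap_extend)
      ord <- order(-back, seed_all_ids)
      recip_top <- seed_all_ids[ord[1L]]
      recip_rank <- match(TRUE, seed_all_ids[ord] %in% seed_ids)
      row <- data.frame(species = sp, gene_id = cand$id,
                        seed_id = seed$id,
                        forward_evalue = top$evalue,
                        forward_score = top$raw_score,
                        reciprocal_top = recip_top,
                        reciprocal_rank = recip_rank,
                        stringsAsFactors = FALSE)
      if (recip_top %in% seed_ids) {
        prov[[length(prov) + 1L]] <- row
        members[[sp]] <- sort(unique(c(members[[sp]], cand$id)))
      } else {
        rej[[length(rej) + 1L]] <- row
      }
    }
  }
  empty <- data.frame(species = character(), gene_id = character(),
                      seed_id = character(), forward_evalue = numeric(),
                      forward_score = numeric(), reciprocal_top = character(),
                      reciprocal_rank = integer(), stringsAsFactors = FALSE)
  members <- members[!vapply(members, is.null, TRUE)]
  structure(list(
    seed_species = seed_species,
    seed_ids = sort(seed_ids),
    members = c(stats::setNames(list(sort(seed_ids)), seed_species), members),
    provenance = if (length(prov)) do.call(rbind, prov) else empty,
    rejects = if (length(rej)) do.call(rbind, rej) else empty),
    class = "homolog_family")
}

#' @export
print.homolog_family <- function(x, ...) {
  n <- sum(lengths(x$members))
  cat(sprintf("<homolog_family> %d genes in %d species (seed: %s)\n",
              n, length(x$members), x$seed_species))
  for (sp in names(x$members)) {
    cat(sprintf("  %s: %s\n", sp, paste(x$members[[sp]], collapse = ", ")))
  }
  invisible(x)
}

#' Family membership as a table
#'
#' @param family a `homolog_family`.
#' @return data frame with columns `species` and `gene_id`, one row per
#'   member (seed genes included).
#' @export
family_table <- function(family) {
  stopifnot(inherits(family, "homolog_family"))
  do.call(rbind, lapply(names(family$members), function(sp) {
    data.frame(species = sp, gene_id = family$members[[sp]],
               stringsAsFactors = FALSE)
  }))
}
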