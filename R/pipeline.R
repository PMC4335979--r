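#' Declarative configuration for the full pipeline
#'
#' Assembles the settings of every stage into one validated object.  With
#' the `simulate` stage enabled the pipeline is self-contained: a species
#' tree, gene family, proteomes and consumption curves are generated from
#' the master seed.  With it disabled, the corresponding inputs must be
#' supplied as files.
#'
#' @param out_dir run directory for artifacts and the manifest.
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "homologs", "align", "tree", "reconcile", "motif",
#'   "rates")`.
#' @param sim a [simulation_config()] for the simulate stage.
#' @param evalue_cutoff forward-search E-value cutoff (default 1e-10).
#' @param block_filter list of [filter_blocks()] parameters.
#' @param tree_method `"nj"` or `"bionj"`.
#' @param correction distance correction: `"p"`, `"poisson"`, or `"gamma"`.
#' @param alpha gamma shape parameter (default 1).
#' @param bootstrap bootstrap replicates (default 100).
#' @param outgroup optional outgroup leaf name for rooting the gene tree.
#' @param motif_pattern motif to scan, in [parse_pattern()] syntax.
#' @param reference_strain reference strain for rate ratios.
#' @param breakpoint segmented-fit breakpoint in hours (default 22).
#' @param sig_figs significant figures for printed ratios.
#' @param rates_panel named list strain -> named numeric vector of true
#'   consumption rates per substrate used by the simulated rates stage.
#' @param inputs named list of optional input files: `proteome_dir` (FASTA
#'   per species), `seed_species`, `seed_ids`, `species_tree`, `gene_tree`,
#'   `leaf_map`, `rates_tsv`.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("simulate", "homologs", "align",
                                       "tree", "reconcile", "motif", "rates"),
                            sim = simulation_config(seed = seed),
                            evalue_cutoff = 1e-10,
                            block_filter = list(max_gap_fraction = 0.5,
                                                min_conserved_fraction = 0.5,
                                                min_block_length = 3L),
                            tree_method = c("nj", "bionj"),
                            correction = c("p", "poisson", "gamma"),
                            alpha = 1.0,
                            bootstrap = 100L,
                            outgroup = NULL,
                            motif_pattern = "NXX(S/T)HX(S/T)QDXXXT",
                            reference_strain = "reference",
                            breakpoint = 22,
                            sig_figs = 2L,
                            rates_panel = NULL,
                            inputs = list()) {
  all_stages <- c("simulate", "homologs", "align", "tree", "reconcile",
                  "motif", "rates")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(rates_panel)) {
    # a reference strain consuming four organic acids at realistic rates,
    # and one transporter-overexpression strain
    rates_panel <- list(
      reference = c(fumarate = 0.22, malate = 0.24,
                    succinate = 0.19, lactate = 0.21),
      overexpression = c(fumarate = 0.24, malate = 0.27,
                         succinate = 0.21, lactate = 0.20))
  }
  cfg <- structure(list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages, sim = sim,
    evalue_cutoff = evalue_cutoff, block_filter = block_filter,
    tree_method = match.arg(tree_method), correction = match.arg(correction),
    alpha = alpha, bootstrap = as.integer(bootstrap), outgroup = outgroup,
    motif_pattern = motif_pattern, reference_strain = reference_strain,
    breakpoint = breakpoint, sig_figs = as.integer(sig_figs),
    rates_panel = rates_panel, inputs = inputs),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate stage dependencies of a pipeline configuration
#'
#' Every enabled stage must be able to obtain its inputs either from an
#' enabled earlier stage or from a supplied file; referenced files must
#' exist.  Called by [pipeline_config()] and again by [run_pipeline()].
#'
#' @param cfg a `pipeline_config`.
#' @return `cfg` invisibly; errors describe the first unmet dependency.
#' @export
validate_pipeline_config <- function(cfg) {
  st <- cfg$stages
  inp <- cfg$inputs
  has_file <- function(key) !is.null(inp[[key]])
  if ("homologs" %in% st && !("simulate" %in% st) &&
      !(has_file("proteome_dir") && has_file("seed_species") &&
        has_file("seed_ids"))) {
    stop("stage 'homologs' needs the simulate stage or inputs proteome_dir, seed_species and seed_ids",
         call. = FALSE)
  }
  if ("align" %in% st && !("homologs" %in% st)) {
    stop("stage 'align' needs stage 'homologs'", call. = FALSE)
  }
  if ("tree" %in% st && !("align" %in% st)) {
    stop("stage 'tree' needs stage 'align'", call. = FALSE)
  }
  if ("reconcile" %in% st) {
    from_sim <- "simulate" %in% st
    from_files <- has_file("species_tree") && has_file("gene_tree")
    if (!from_sim && !from_files) {
      stop("stage 'reconcile' needs the simulate stage or species_tree and gene_tree files",
           call. = FALSE)
    }
  }
  if ("motif" %in% st && !("simulate" %in% st) && !has_file("proteome_dir")) {
    stop("stage 'motif' needs the simulate stage or a proteome_dir input",
         call. = FALSE)
  }
  if ("rates" %in% st && !("simulate" %in% st) && !has_file("rates_tsv")) {
    stop("stage 'rates' needs the simulate stage or a rates_tsv input",
         call. = FALSE)
  }
  for (key in c("species_tree", "gene_tree", "leaf_map", "rates_tsv",
                "proteome_dir")) {
    if (has_file(key) && !file.exists(inp[[key]])) {
      stop(sprintf("input file not found: %s = %s", key, inp[[key]]),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order, writing each artifact
#' (FASTA, Newick, TSV) under `out_dir` and recording everything in a
#' machine-readable `manifest.json`: the configuration, the per-stage seeds
#' derived from the master seed, the artifact files with md5 checksums, and
#' headline numbers per stage.  A rerun with the same configuration and
#' seed reproduces byte-identical artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly (a nested list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "jenscape",
                   version = as.character(utils::packageVersion("jenscape")),
                   seed = cfg$seed, stages = list())
  artifacts <- character()
  note <- function(stage, files, info = list()) {
    manifest$stages[[stage]] <<- c(list(outputs = basename(files)), info)
    artifacts <<- c(artifacts, files)
  }
  st <- cfg$stages
  truth <- NULL; proteomes <- NULL; family <- NULL
  seed_species <- NULL; seed_ids <- NULL
  msa <- NULL; filtered <- NULL; boot <- NULL

  if ("simulate" %in% st) {
    sim_seed <- derive_seed(cfg$seed, "simulate")
    sp_tree <- simulate_species_tree(cfg$sim$n_species, seed = sim_seed,
                                     branch_length_mean = cfg$sim$branch_length_mean)
    truth <- simulate_gene_family(
      sp_tree, simulation_config(
        n_species = cfg$sim$n_species, dup_rate = cfg$sim$dup_rate,
        loss_rate = cfg$sim$loss_rate, root_copies = cfg$sim$root_copies,
        seq_length = cfg$sim$seq_length, subst_rate = cfg$sim$subst_rate,
        n_decoys_per_species = cfg$sim$n_decoys_per_species,
        branch_length_mean = cfg$sim$branch_length_mean, seed = sim_seed))
    proteomes <- evolve_sequences(truth$gene_tree,
                                  cfg$sim, species = sp_tree$tip.label,
                                  seed = derive_seed(sim_seed, "seq"))
    files <- file.path(cfg$out_dir, "species_tree.nwk")
    writeLines(write_newick(sp_tree), files)
    if (!is.null(truth$gene_tree)) {
      gt <- file.path(cfg$out_dir, "true_gene_tree.nwk")
      writeLines(write_newick(truth$gene_tree), gt)
      files <- c(files, gt)
    }
    ev <- file.path(cfg$out_dir, "true_events.tsv")
    write_tsv(truth$events, ev)
    fa <- vapply(names(proteomes), function(sp) {
      p <- file.path(cfg$out_dir, sprintf("proteome_%s.faa", sp))
      write_fasta(proteomes[[sp]], p)
      p
    }, "")
    note("simulate", c(files, ev, fa),
         list(seed = sim_seed, n_genes = nrow(truth$genes),
              n_duplications = truth$n_duplications,
              n_losses = truth$n_losses))
    counts <- table(truth$genes$species)
    if (length(counts) > 0L) {
      seed_species <- names(counts)[order(-as.vector(counts),
                                          names(counts))][1L]
      seed_ids <- truth$genes$gene[truth$genes$species == seed_species]
    }
  } else if (!is.null(cfg$inputs$proteome_dir)) {
    files <- list.files(cfg$inputs$proteome_dir, pattern = "\\.fa(a|sta)?$",
                        full.names = TRUE)
    proteomes <- stats::setNames(
      lapply(files, function(f) {
        read_fasta(f, species = sub("\\.fa(a|sta)?$", "", basename(f)))
      }),
      sub("\\.fa(a|sta)?$", "", basename(files)))
    seed_species <- cfg$inputs$seed_species
    seed_ids <- cfg$inputs$seed_ids
  }

  if ("homologs" %in% st) {
    if (is.null(seed_ids) || length(seed_ids) == 0L) {
      stop("homologs stage: no seed genes available", call. = FALSE)
    }
    family <- reciprocal_screen(
      seed_ids, proteomes[[seed_species]],
      proteomes[names(proteomes) != seed_species],
      cutoff = cfg$evalue_cutoff)
    f1 <- write_tsv(family_table(family),
                    file.path(cfg$out_dir, "family.tsv"))
    f2 <- write_tsv(family$rejects, file.path(cfg$out_dir, "rejects.tsv"))
    note("homologs", c(f1, f2),
         list(n_members = sum(lengths(family$members))))
  }

  members <- NULL
  if ("align" %in% st && !is.null(family)) {
    tab <- family_table(family)
    by_id <- stats::setNames(
      unlist(lapply(proteomes, identity), recursive = FALSE),
      unlist(lapply(proteomes, function(p) vapply(p, `[[`, "", "id"))))
    members <- by_id[tab$gene_id]
    msa <- progressive_align(members)
    f1 <- file.path(cfg$out_dir, "family_alignment.faa")
    writeLines(as.vector(rbind(paste0(">", msa$ids), msa$rows)), f1)
    fb <- filter_blocks(msa,
                        max_gap_fraction = cfg$block_filter$max_gap_fraction,
                        min_conserved_fraction = cfg$block_filter$min_conserved_fraction,
                        min_block_length = cfg$block_filter$min_block_length)
    filtered <- fb$msa
    f2 <- write_tsv(data.frame(kept_column = fb$kept_columns),
                    file.path(cfg$out_dir, "kept_columns.tsv"))
    note("align", c(f1, f2),
         list(n_columns = msa$n_columns,
              n_kept_columns = filtered$n_columns))
  }

  if ("tree" %in% st && !is.null(filtered) && length(filtered$ids) >= 3L) {
    tree_seed <- derive_seed(cfg$seed, "tree")
    boot <- bootstrap_support(filtered, builder = cfg$tree_method,
                              n_replicates = cfg$bootstrap, seed = tree_seed,
                              correction = cfg$correction, alpha = cfg$alpha)
    tr <- boot$main_tree
    if (!is.null(cfg$outgroup) && cfg$outgroup %in% tr$tip.label) {
      tr <- root_with_outgroup(tr, cfg$outgroup)
    }
    f1 <- file.path(cfg$out_dir, "gene_tree.nwk")
    writeLines(write_newick(tr), f1)
    note("tree", f1, list(seed = tree_seed, method = cfg$tree_method,
                          n_replicates = cfg$bootstrap,
                          n_skipped = boot$n_skipped))
  }

  if ("reconcile" %in% st) {
    if (!is.null(truth) && !is.null(truth$gene_tree)) {
      gt <- truth$gene_tree
      sp <- truth$species_tree
    } else {
      gt <- read_newick(paste(readLines(cfg$inputs$gene_tree), collapse = ""))
      sp <- read_newick(paste(readLines(cfg$inputs$species_tree),
                              collapse = ""))
    }
    lm <- if (!is.null(cfg$inputs$leaf_map)) {
      m <- utils::read.delim(cfg$inputs$leaf_map, stringsAsFactors = FALSE)
      stats::setNames(m[[2]], m[[1]])
    } else leaf_map_from_names(gt$tip.label)
    rec <- lca_reconcile(gt, sp, lm)
    f1 <- write_tsv(scenario_report(rec),
                    file.path(cfg$out_dir, "reconciliation_branches.tsv"))
    f2 <- write_tsv(rec$losses[, c("gene_child", "species_branch")],
                    file.path(cfg$out_dir, "reconciliation_losses.tsv"))
    f3 <- file.path(cfg$out_dir, "gene_tree_events.nwk")
    writeLines(write_newick(annotate_events(rec)), f3)
    note("reconcile", c(f1, f2, f3),
         list(n_duplications = rec$n_duplications, n_losses = rec$n_losses))
  }

  if ("motif" %in% st && !is.null(proteomes)) {
    pat <- parse_pattern(cfg$motif_pattern)
    hits <- list()
    for (sp in names(proteomes)) {
      for (rec in proteomes[[sp]]) {
        h <- scan_motif(rec, pat)
        if (nrow(h) > 0L)

          hits[[length(hits) + 1L]] <- h[, c("seq_id", "start", "end",
                                             "matched")]
      }
    }
    tab <- if (length(hits)) do.call(rbind, hits) else
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 matched = character(), stringsAsFactors = FALSE)
    f1 <- write_tsv(tab, file.path(cfg$out_dir, "motifs.tsv"))
    note("motif", f1, list(n_matches = nrow(tab)))
  }

  if ("rates" %in% st) {
    fits <- list()
    if (!is.null(cfg$inputs$rates_tsv)) {
      tab <- utils::read.delim(cfg$inputs$rates_tsv,
                               stringsAsFactors = FALSE)
      for (key in unique(paste(tab$strain, tab$substrate, sep = "\r"))) {
        part <- tab[paste(tab$strain, tab$substrate, sep = "\r") == key, ]
        ts <- time_series(part$time_h, part$concentration_gL,
                          substrate = part$substrate[[1]],
                          strain = part$strain[[1]])
        fits[[length(fits) + 1L]] <- fit_rate(ts)
      }
      ref_strain <- cfg$reference_strain
    } else {
      rate_seed <- derive_seed(cfg$seed, "rates")
      times <- seq(0, 40, by = 4)
      k <- 0L
      for (strain in names(cfg$rates_panel)) {
        rates <- cfg$rates_panel[[strain]]
        for (su in names(rates)) {
          k <- k + 1L
          tr <- consumption_truth(su, c0 = 10, true_rate = rates[[su]],
                                  times = times, noise_sd = 0.05,
                                  strain = strain)
          ts <- simulate_consumption_series(tr,
                                            seed = derive_seed(rate_seed, k))
          fits[[length(fits) + 1L]] <- fit_rate(ts)
        }
      }
      ref_strain <- names(cfg$rates_panel)[[1]]
    }
    tab <- rate_table(fits, ref_strain, sig_figs = cfg$sig_figs)
    f1 <- write_tsv(tab, file.path(cfg$out_dir, "rates.tsv"))
    note("rates", f1, list(reference = ref_strain, n_fits = length(fits)))
  }

  manifest$artifacts <- lapply(
    stats::setNames(artifacts, basename(artifacts)),
    function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
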