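#' Pipeline run configuration
#'
#' Collects every stage's inputs and under-specified constants in one
#' auditable object.  Inputs are either a simulation block (`simulate =`
#' a [sim_config()]) or file paths to real data.
#'
#' @param simulate A [sim_config()], or `NULL` when file inputs are
#'   given.
#' @param gene_tree,species_tree,clade_map,pairs,protein,cds File paths
#'   (newick / newick / TSV / BLAST-tabular or TSV / aligned FASTA /
#'   aligned CDS FASTA).  `protein` must be a protein alignment covering
#'   the gene tree's genes; `cds` a codon alignment.
#' @param loci Named character vector of per-species BED/GFF3 paths.
#' @param support_min,outgroup_clade,crown_clades,deep_clade,
#'   support_absent,unassigned_policy Passed to [delineate_lineages()].
#' @param ancestors Clade -> species-tree ancestor name map for
#'   [tally_gains_losses()].
#' @param chain MCScanX-style [chain_params()].
#' @param tandem_max_intervening Tandem adjacency bound.
#' @param kaks_species Length-2 character vector: the species pair for
#'   within-lineage Ka/Ks (default the first two clade-A species found).
#' @param gap_threshold Column-trim threshold for conserved regions.
#' @param out_dir Optional directory for stage outputs and the JSON
#'   report.
#' @param seed Seed forwarded to the simulation block.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, gene_tree = NULL,
                       species_tree = NULL, clade_map = NULL,
                       loci = NULL, pairs = NULL, protein = NULL,
                       cds = NULL, support_min = 60, outgroup_clade = "F",
                       crown_clades = c("A", "B"), deep_clade = "D",
                       support_absent = "fail",
                       unassigned_policy = "nearest_anchor",
                       ancestors = c(A = "LCA_A", B = "LCA_B", D = "LCA_D"),
                       chain = chain_params(),
                       tandem_max_intervening = 5,
                       kaks_species = NULL, gap_threshold = 0.3,
                       out_dir = NULL, seed = NULL) {
  if (is.null(simulate)) {
    for (f in c(gene_tree, species_tree, clade_map, pairs, protein, cds,
                unname(loci))) {
      if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
    }
    if (is.null(gene_tree) || is.null(species_tree) || is.null(clade_map)) {
      stop("either `simulate` or gene_tree + species_tree + clade_map ",
           "must be given")
    }
  } else if (!is.null(seed)) {
    simulate$seed <- seed
  } else {
    seed <- simulate$seed
  }
  structure(list(simulate = simulate, gene_tree = gene_tree,
                 species_tree = species_tree, clade_map = clade_map,
                 loci = loci, pairs = pairs, protein = protein, cds = cds,
                 support_min = support_min, outgroup_clade = outgroup_clade,
                 crown_clades = crown_clades, deep_clade = deep_clade,
                 support_absent = support_absent,
                 unassigned_policy = unassigned_policy,
                 ancestors = ancestors, chain = chain,
                 tandem_max_intervening = tandem_max_intervening,
                 kaks_species = kaks_species, gap_threshold = gap_threshold,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror the [run_config()] arguments; the `simulate` and
#' `chain` blocks map onto [sim_config()] and [chain_params()].
#'
#' @param file YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (isTRUE(sim)) sim <- list()
    y$simulate <- do.call(sim_config, sim)
  }
  if (!is.null(y$chain)) y$chain <- do.call(chain_params, y$chain)
  if (!is.null(y$ancestors)) y$ancestors <- unlist(y$ancestors)
  if (!is.null(y$loci)) y$loci <- unlist(y$loci)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages run in order: (simulate or load) -> delineate lineages ->
#' reconcile and tally gains/losses -> tandem/synteny classification ->
#' per-lineage sequence statistics.  Identical configuration and seed
#' give an identical report.
#'
#' @param config A [run_config()] (or a [sim_config()], used as the
#'   simulation block of a default run).
#' @return A `run_report` list: headline numbers per stage, the stage
#'   objects, the constants used, warnings, and a configuration hash.
#'   When `config$out_dir` is set, stage TSV/JSON files are also
#'   written.
#' @export
run_all <- function(config = run_config(simulate = sim_config())) {
  if (inherits(config, "sim_config")) {
    config <- run_config(simulate = config, seed = config$seed)
  }
  stopifnot(inherits(config, "run_config"))
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, conditionMessage(w))
  stage_failed <- NULL
  report <- list(tool_version =
                   as.character(utils::packageVersion("linfam")),
                 seed = config$seed)

  # ingest -----------------------------------------------------------
  fam <- NULL
  if (!is.null(config$simulate)) {
    fam <- simulate_family(config$simulate)
    gt <- fam$gene_tree
    sp_tree <- fam$species_tree
    clade_map <- fam$clade_map
    loci <- fam$loci
    pairs <- fam$pairs
    protein <- fam$protein
    cds <- fam$cds
  } else {
    gt <- read_gene_tree(config$gene_tree)
    sp_tree <- read_species_tree(config$species_tree)
    clade_map <- read_clade_map(config$clade_map)
    loci <- if (!is.null(config$loci)) {
      stats::setNames(lapply(config$loci, read_gene_loci),
                      names(config$loci))
    }
    pairs <- if (!is.null(config$pairs)) {
      read_homolog_pairs(config$pairs, config$chain$e_value_max)
    }
    protein <- if (!is.null(config$protein)) {
      Biostrings::readAAStringSet(config$protein)
    }
    cds <- if (!is.null(config$cds)) {
      Biostrings::readDNAStringSet(config$cds)
    }
    og <- gt$genes$tip_label[
      clade_map[gt$genes$species_id] == config$outgroup_clade]
    if (length(og) > 0L && length(og) < nrow(gt$genes)) {
      gt <- root_by_outgroup(gt, og)
    }
  }
  report$n_genes <- nrow(gt$genes)
  report$n_species <- length(unique(gt$genes$species_id))

  # delineate --------------------------------------------------------
  partition <- withCallingHandlers(
    delineate_lineages(gt, clade_map,
                       support_min = config$support_min,
                       outgroup_clade = config$outgroup_clade,
                       crown_clades = config$crown_clades,
                       deep_clade = config$deep_clade,
                       support_absent = config$support_absent,
                       unassigned_policy = config$unassigned_policy),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  report$n_lineages <- nrow(partition$lineages)
  report$n_ingroup_lineages <-
    sum(!partition$lineages$is_outgroup)

  # reconcile --------------------------------------------------------
  rec <- lca_reconcile(gt, sp_tree)
  gl <- tally_gains_losses(rec, partition, clade_map,
                           ancestors = config$ancestors)
  report$gains_total <- gl$gains_total
  report$gains_founding <- gl$gains_founding
  report$gains_per_clade <- as.list(gl$gains_per_clade)
  report$losses_total <- gl$losses_total

  # synteny ----------------------------------------------------------
  syn <- NULL
  if (!is.null(loci) && !is.null(pairs)) {
    syn <- tryCatch(withCallingHandlers(
      classify_pairs(partition, pairs, loci, params = config$chain,
                     tandem_max_intervening = config$tandem_max_intervening),
      warning = function(w) { note(w); invokeRestart("muffleWarning") }),
      error = function(e) { stage_failed <<- paste("synteny:",
                                                   conditionMessage(e)); NULL })
    if (!is.null(syn)) {
      report$n_tandem_events <- syn$n_tandem_events
      report$n_syntenic <- syn$n_syntenic
      report$n_nonsyntenic <- syn$n_nonsyntenic
      report$n_lineages_syntenic <- syn$n_lineages_syntenic
    }
  }

  # seqstats ---------------------------------------------------------
  cons <- NULL
  kaks <- NULL
  if (!is.null(protein)) {
    prot_named <- stats::setNames(as.character(protein), names(protein))
    cons <- lineage_conservation_stats(partition, prot_named,
                                       gap_threshold = config$gap_threshold)
    ls <- length_summary(Biostrings::AAStringSet(gsub("[-.*]", "",
                                                      prot_named)))
    report$protein_length <- ls
    report$conserved_len_range <-
      range(cons$conserved_len[cons$n > 1], na.rm = TRUE)
    report$median_similarity_range <-
      suppressWarnings(range(cons$median_similarity, na.rm = TRUE))
  }
  if (!is.null(cds)) {
    ks <- config$kaks_species
    if (is.null(ks)) {
      asg <- partition$assignment
      cand <- sort(unique(asg$species_id[asg$clade == "A"]))
      if (length(cand) >= 2L) ks <- cand[1:2]
    }
    if (!is.null(ks) && length(ks) == 2L) {
      kaks <- lineage_kaks(partition, cds, ks[1], ks[2])
      report$kaks_species <- ks
      report$kaks_n_pairs <- nrow(kaks)
      report$kaks_median <-
        if (nrow(kaks) > 0L) stats::median(kaks$ratio, na.rm = TRUE)
        else NA_real_
    }
  }

  report$warnings <- warnings
  report$stage_failed <- stage_failed
  report$constants <- list(
    support_min = config$support_min,
    support_absent = config$support_absent,
    unassigned_policy = config$unassigned_policy,
    tandem_max_intervening = config$tandem_max_intervening,
    gap_threshold = config$gap_threshold,
    chain = unclass(config$chain),
    ancestors = as.list(config$ancestors))
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  report$config_hash <- .config_hash(cfg_for_hash)

  out <- structure(list(report = report, partition = partition,
                        reconciliation = rec, gain_loss = gl,
                        synteny = syn, conservation = cons, kaks = kaks,
                        family = fam, config = config),
                   class = "run_report")
  if (!is.null(config$out_dir)) .write_run_outputs(out, config$out_dir)
  out
}

# polynomial rolling hash over the canonical JSON serialisation of the
# config (a fingerprint for report provenance, not cryptographic)
.config_hash <- function(x) {
  bytes <- utf8ToInt(as.character(jsonlite::serializeJSON(x)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

.write_run_outputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lineage_partition(x$partition, file.path(dir, "lineages.tsv"))
  if (!is.null(x$family)) {
    write_simulated_family(x$family, file.path(dir, "sim"))
  }
  if (!is.null(x$synteny)) {
    utils::write.table(x$synteny$matrix_syntenic,
                       file.path(dir, "matrix_syntenic.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(x$synteny$matrix_nonsyntenic,
                       file.path(dir, "matrix_nonsyntenic.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(x$conservation)) {
    utils::write.table(x$conservation, file.path(dir, "conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(x$kaks)) {
    utils::write.table(x$kaks, file.path(dir, "kaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(x$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("linfam run_report (config", r$config_hash, ")\n")
  cat("  genes:", r$n_genes, " species:", r$n_species, "\n")
  cat("  lineages:", r$n_lineages,
      "(", r$n_ingroup_lineages, "ingroup )\n")
  cat("  gains:", r$gains_total, " losses:", r$losses_total, "\n")
  if (!is.null(r$n_tandem_events)) {
    cat("  tandem events:", r$n_tandem_events, " syntenic pairs:",
        r$n_syntenic, "/", r$n_syntenic + r$n_nonsyntenic, "\n")
  }
  if (!is.null(r$kaks_median)) {
    cat("  Ka/Ks median (", paste(r$kaks_species, collapse = " x "), "):",
        round(r$kaks_median, 3), "over", r$kaks_n_pairs, "pairs\n")
  }
  if (length(r$warnings) > 0L) {
    cat("  warnings:", length(r$warnings), "\n")
  }
  invisible(x)
}
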