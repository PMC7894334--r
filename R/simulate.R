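#' Default clade-structured species tree
#'
#' A synthetic, ultrametric 23-species Brassicaceae-like phylogeny: one
#' early-diverging outgroup species (clade F) sister to a 22-species
#' ingroup split into crown clades A (9 species) and B (7 species) plus
#' the deeper-branching clade D (6 species).  Branch lengths are in
#' arbitrary time units (roughly Myr); internal nodes are named, with the
#' ancestors `LCA_Brassicaceae`, `LCA_ABD`, `LCA_AB`, `LCA_A`, `LCA_B`,
#' `LCA_D` used by the reconciliation stage.
#'
#' @return An [ape::phylo] with named internal nodes.
#' @export
default_species_tree <- function() {
  ladder <- function(tips, crown) {
    ages <- seq(crown, crown / length(tips), length.out = length(tips) - 1)
    build <- function(tips, ages) {
      if (length(tips) == 1L) return(list(str = tips, age = 0))
      rest <- build(tips[-1L], ages[-1L])
      list(str = sprintf("(%s:%g,%s:%g)", tips[1L], ages[1L], rest$str,
                         ages[1L] - rest$age),
           age = ages[1L])
    }
    build(tips, ages)
  }
  A <- ladder(sprintf("A%02d", 1:9), 24)
  B <- ladder(sprintf("B%02d", 1:7), 22)
  D <- ladder(sprintf("D%02d", 1:6), 20)
  ab_age <- 28; abd_age <- 32; root_age <- 54
  ab <- sprintf("(%s:%g,%s:%g)LCA_AB:%g",
                sub("\\)$", ")LCA_A", A$str), ab_age - A$age,
                sub("\\)$", ")LCA_B", B$str), ab_age - B$age,
                abd_age - ab_age)
  abd <- sprintf("(%s,%s:%g)LCA_ABD:%g",
                 ab, sub("\\)$", ")LCA_D", D$str), abd_age - D$age,
                 root_age - abd_age)
  nwk <- sprintf("(F01:%g,%s)LCA_Brassicaceae;", root_age, abd)
  phy <- ape::read.tree(text = nwk)
  blank <- !nzchar(phy$node.label)
  phy$node.label[blank] <- paste0("N", which(blank))
  phy
}

#' Default species-to-clade map for [default_species_tree()]
#'
#' @return Named character vector species -> clade label.
#' @export
default_clade_map <- function() {
  sp <- default_species_tree()$tip.label
  as_clade_map(stats::setNames(substr(sp, 1, 1), sp),
               alphabet = c("A", "B", "D", "F"))
}

#' Simulation configuration
#'
#' Defaults emulate the study regime: a single ancestral copy in the
#' family ancestor, duplication/loss rates yielding per-species family
#' sizes in the few-to-hundred range, a 30% chance that a duplicate
#' inserts in tandem next to its parent, background genomes of 5
#' chromosomes x 100 gene slots, and sequence divergence deep enough to
#' bring within-lineage conserved-region identity into the 40-72% band.
#'
#' @param species_tree Rooted, named species tree with branch lengths.
#' @param clade_map Named character vector species -> clade.
#' @param lambda Duplication rate (events / gene / time unit).
#' @param lambda_sigma Log-scale standard deviation of the per-branch
#'   duplication-rate multiplier (lognormal, mean 1).  Captures bursty,
#'   branch-specific amplification; 0 gives a homogeneous rate.
#' @param mu Loss rate.
#' @param p_tandem Probability a duplicate inserts adjacent to its
#'   parent; otherwise it lands on a uniform-random chromosome position.
#' @param n_chrom,n_bg Chromosome count and background gene slots per
#'   chromosome of each simulated genome.
#' @param p_relocate Per-species probability that a background gene has
#'   moved away from its ancestral slot (synteny noise).
#' @param n_codons CDS length in codons.
#' @param substitution_rate Nucleotide substitution rate (/site/time
#'   unit) for [evolve_sequences()].
#' @param omega Nonsynonymous/synonymous acceptance ratio.
#' @param support_q Probability an internal node receives the full
#'   support value; otherwise support is uniform on `[30, 100)`.
#' @param founder_node Named species-tree node at which founder (true
#'   lineage) identities are recorded.
#' @param stem_boost Multiplier on the duplication rate along the
#'   branches between the family origin (species-tree root) and
#'   `founder_node`: the family's expansion is concentrated early, on
#'   the stem preceding the ingroup crown radiation.
#' @param synteny_species Species whose genomes (with background genes
#'   and ortholog anchors) are emitted for the synteny stage.
#' @param max_genes Families larger than this are treated like extinct
#'   ones and resampled (with a logged count): runaway birth bursts are
#'   outside the emulated regime.
#' @param seed Integer seed; the same seed reproduces identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       clade_map = default_clade_map(),
                       lambda = 0.035, lambda_sigma = 0.6, mu = 0.01,
                       p_tandem = 0.3,
                       n_chrom = 5, n_bg = 100, p_relocate = 0.05,
                       n_codons = 300, substitution_rate = 0.016,
                       omega = 0.3, support_q = 0.9,
                       founder_node = "LCA_ABD", stem_boost = 3,
                       synteny_species = NULL, max_genes = 1500L,
                       seed = 1L) {
  if (lambda < 0 || mu < 0) stop("rates must be >= 0")
  if (p_tandem < 0 || p_tandem > 1) stop("p_tandem must be in [0, 1]")
  if (omega < 0) stop("omega must be >= 0")
  if (is.null(synteny_species)) {
    tips <- species_tree$tip.label
    pick <- function(pfx, k) utils::head(grep(pfx, tips, value = TRUE), k)
    synteny_species <- c(pick("^A", 3), pick("^B", 2), pick("^D", 2),
                         pick("^F", 1))
    if (length(synteny_species) == 0L) synteny_species <- tips
  }
  if (lambda_sigma < 0) stop("lambda_sigma must be >= 0")
  structure(list(species_tree = species_tree, clade_map = clade_map,
                 lambda = lambda, lambda_sigma = lambda_sigma, mu = mu,
                 p_tandem = p_tandem,
                 n_chrom = n_chrom, n_bg = n_bg, p_relocate = p_relocate,
                 n_codons = n_codons, substitution_rate = substitution_rate,
                 omega = omega, support_q = support_q,
                 founder_node = founder_node, stem_boost = stem_boost,
                 synteny_species = synteny_species, max_genes = max_genes,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a gene family with full ground truth
#'
#' Runs a Gillespie birth-death process (duplication rate `lambda`, loss
#' rate `mu` per gene copy) along every branch of the species tree,
#' starting from a single ancestral copy at the root.  Duplicates insert
#' in tandem next to their parent with probability `p_tandem`, otherwise
#' at a uniform-random chromosome position; placements are inherited
#' through speciations.  Families extinct in all species (or with fewer
#' than two surviving genes) are resampled with a logged count.
#'
#' @param config A [sim_config()].
#' @return A `simulated_family`: list with `gene_tree` (a `gene_tree`
#'   with simulated supports), `genes` (per-gene table incl. true
#'   founder = true lineage), `loci` (named list of per-species locus
#'   tables incl. background genes for `synteny_species`), `pairs`
#'   (homolog + ortholog anchor pairs), `cds`/`protein`
#'   ([Biostrings::DNAStringSet] / [Biostrings::AAStringSet]),
#'   `events` (duplication/loss/founder logs), `species_tree`,
#'   `clade_map`, `config`.
#' @export
simulate_family <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$species_tree
  depth <- max(ape::node.depth.edgelength(sp))
  if (config$lambda > 0 &&
      exp((config$lambda * (config$stem_boost %||% 1) - config$mu) *
            depth) > 1e4) {
    stop("expected family size exceeds 10^4; lower lambda or tree depth")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n_resampled <- 0L
  repeat {
    fam <- .simulate_family_once(config)
    if (!is.null(fam)) break
    n_resampled <- n_resampled + 1L
    if (n_resampled > 1000L) stop("family went extinct in 1000 consecutive runs")
  }
  fam$events$n_resampled <- n_resampled
  fam
}

.simulate_family_once <- function(config) {
  sp <- config$species_tree
  ntip_sp <- length(sp$tip.label)
  sp_times <- ape::node.depth.edgelength(sp)
  sp_labels <- c(sp$tip.label, sp$node.label)
  spar <- .parent_vec(sp)

  # gene-tree node and event stores: preallocated parallel vectors with
  # doubling growth (per-element growth is quadratic in family size)
  env <- new.env(parent = emptyenv())
  env$n_nodes <- 0L
  env$parent <- integer(256)
  env$time <- numeric(256)
  env$type <- character(256)
  env$label <- character(256)
  new_node <- function(parent, time, type, label = "") {
    id <- env$n_nodes + 1L
    if (id > length(env$parent)) {
      len <- 2L * length(env$parent)
      length(env$parent) <- len
      length(env$time) <- len
      length(env$type) <- len
      length(env$label) <- len
    }
    env$parent[id] <- parent
    env$time[id] <- time
    env$type[id] <- type
    env$label[id] <- label
    env$n_nodes <- id
    id
  }

  env$n_dups <- 0L
  env$d_time <- numeric(64); env$d_branch <- character(64)
  env$d_parent <- character(64); env$d_new <- character(64)
  env$d_place <- character(64); env$d_chrom <- integer(64)
  env$d_key <- numeric(64)
  env$n_losses <- 0L
  env$l_time <- numeric(64); env$l_branch <- character(64)
  env$l_copy <- character(64)
  env$n_founders <- 0L
  env$f_id <- character(16); env$f_copy <- character(16)
  env$n_genes <- 0L
  env$g_id <- character(256); env$g_sp <- character(256)
  env$g_copy <- character(256); env$g_founder <- character(256)
  env$g_chrom <- integer(256); env$g_key <- numeric(256)
  env$copy_n <- 0L
  new_copy_id <- function() {
    env$copy_n <- env$copy_n + 1L
    sprintf("c%05d", env$copy_n)
  }

  mu <- config$mu
  # bursty, branch-specific duplication rates: lognormal multiplier with
  # mean 1, drawn once per species-tree branch (indexed by child node)
  n_sp_nodes <- ntip_sp + sp$Nnode
  s2 <- config$lambda_sigma
  lam_mult <- if (s2 > 0) {
    exp(stats::rnorm(n_sp_nodes, -s2^2 / 2, s2))
  } else {
    rep(1, n_sp_nodes)
  }
  # early burst: expansion concentrated on the stem branches between the
  # family origin and the ingroup crown ancestor
  if (!is.null(config$stem_boost) && config$stem_boost != 1) {
    boosted <- integer(0)
    v <- tryCatch(species_node(sp, config$founder_node),
                  error = function(e) NA_integer_)
    while (!is.na(v) && v != 0L && v != ntip_sp + 1L) {
      boosted <- c(boosted, v)
      v <- spar[v]
    }
    lam_mult[boosted] <- lam_mult[boosted] * config$stem_boost
  }
  cap <- config$max_genes %||% Inf
  env$abort <- FALSE
  evolve_branch <- function(copies, t0, t1, branch_label, sp_child) {
    lam <- config$lambda * lam_mult[sp_child]
    t <- t0
    repeat {
      n <- length(copies)
      if (n > cap) { env$abort <- TRUE; break }  # runaway burst: give up
      if (n == 0L || (lam + mu) == 0) break
      dt <- stats::rexp(1, n * (lam + mu))
      if (t + dt > t1) break
      t <- t + dt
      i <- sample.int(n, 1L)
      if (stats::runif(1) < lam / (lam + mu)) {   # duplication
        par_copy <- copies[[i]]
        d <- new_node(par_copy$node, t, "dup")
        tandem <- stats::runif(1) < config$p_tandem
        if (tandem) {
          chrom <- par_copy$chrom
          key <- par_copy$key + stats::runif(1) * 1e-6
        } else {
          chrom <- sample.int(config$n_chrom, 1L)
          key <- stats::runif(1, 0, config$n_bg + 1)
        }
        id_new <- new_copy_id()
        copies[[i]]$node <- d
        copies[[length(copies) + 1L]] <-
          list(id = id_new, node = d, chrom = chrom, key = key,
               founder = par_copy$founder)
        k <- env$n_dups + 1L
        if (k > length(env$d_time)) {
          len <- 2L * length(env$d_time)
          length(env$d_time) <- len; length(env$d_branch) <- len
          length(env$d_parent) <- len; length(env$d_new) <- len
          length(env$d_place) <- len; length(env$d_chrom) <- len
          length(env$d_key) <- len
        }
        env$d_time[k] <- t; env$d_branch[k] <- branch_label
        env$d_parent[k] <- par_copy$id; env$d_new[k] <- id_new
        env$d_place[k] <- if (tandem) "tandem" else "dispersed"
        env$d_chrom[k] <- chrom; env$d_key[k] <- key
        env$n_dups <- k
      } else {                                    # loss
        lost <- copies[[i]]
        new_node(lost$node, t, "loss")
        k <- env$n_losses + 1L
        if (k > length(env$l_time)) {
          len <- 2L * length(env$l_time)
          length(env$l_time) <- len; length(env$l_branch) <- len
          length(env$l_copy) <- len
        }
        env$l_time[k] <- t; env$l_branch[k] <- branch_label
        env$l_copy[k] <- lost$id
        env$n_losses <- k
        copies[[i]] <- NULL
      }
    }
    copies
  }

  visit <- function(sp_node, copies) {
    if (env$abort) return(invisible())
    t_node <- sp_times[sp_node]
    if (sp_labels[sp_node] == config$founder_node && length(copies) > 0L) {
      for (j in seq_along(copies)) {
        copies[[j]]$founder <- sprintf("F%02d", j)
        k <- env$n_founders + 1L
        if (k > length(env$f_id)) {
          len <- 2L * length(env$f_id)
          length(env$f_id) <- len; length(env$f_copy) <- len
        }
        env$f_id[k] <- copies[[j]]$founder
        env$f_copy[k] <- copies[[j]]$id
        env$n_founders <- k
      }
    }
    if (sp_node <= ntip_sp) {
      if (env$n_genes + length(copies) > cap) {
        env$abort <- TRUE   # family already over the size cap
        return(invisible())
      }
      for (cp in copies) {
        k <- env$n_genes + 1L
        if (k > length(env$g_id)) {
          len <- 2L * length(env$g_id)
          length(env$g_id) <- len; length(env$g_sp) <- len
          length(env$g_copy) <- len; length(env$g_founder) <- len
          length(env$g_chrom) <- len; length(env$g_key) <- len
        }
        gid <- sprintf("g%04d", k)
        lab <- paste0(gid, "_", sp_labels[sp_node])
        new_node(cp$node, t_node, "tip", lab)
        env$g_id[k] <- gid
        env$g_sp[k] <- sp_labels[sp_node]
        env$g_copy[k] <- cp$id
        env$g_founder[k] <- cp$founder %||% NA_character_
        env$g_chrom[k] <- cp$chrom
        env$g_key[k] <- cp$key
        env$n_genes <- k
      }
      return(invisible())
    }
    for (cp in copies) {
      s <- new_node(cp$node, t_node, "spec")
      for (kid in .children_of(sp, sp_node)) {
        branch_copies <- list(modifyList(cp, list(node = s)))
        branch_copies <- evolve_branch(branch_copies, t_node, sp_times[kid],
                                       sp_labels[kid], kid)
        visit(kid, branch_copies)
      }
    }
  }

  root_copy <- list(id = new_copy_id(),
                    node = 0L,  # no parent edge above the first speciation
                    chrom = sample.int(config$n_chrom, 1L),
                    key = stats::runif(1, 0, config$n_bg + 1),
                    founder = NULL)
  visit(ntip_sp + 1L, list(root_copy))

  if (env$abort) return(NULL)
  ng <- env$n_genes
  if (ng < 2L) return(NULL)
  if (ng > (config$max_genes %||% Inf)) return(NULL)
  genes <- data.frame(
    gene_id = env$g_id[seq_len(ng)], species_id = env$g_sp[seq_len(ng)],
    copy_id = env$g_copy[seq_len(ng)],
    founder = env$g_founder[seq_len(ng)],
    chrom = env$g_chrom[seq_len(ng)], key = env$g_key[seq_len(ng)],
    stringsAsFactors = FALSE)

  nwk <- .build_newick(env)
  gt <- read_gene_tree(nwk)
  gt <- simulate_supports(gt, q = config$support_q)

  nd <- env$n_dups; nl <- env$n_losses; nf <- env$n_founders
  events <- list(
    duplications = data.frame(
      time = env$d_time[seq_len(nd)],
      species_branch = env$d_branch[seq_len(nd)],
      parent_copy = env$d_parent[seq_len(nd)],
      new_copy = env$d_new[seq_len(nd)],
      placement = env$d_place[seq_len(nd)],
      chrom = env$d_chrom[seq_len(nd)], key = env$d_key[seq_len(nd)],
      stringsAsFactors = FALSE),
    losses = data.frame(
      time = env$l_time[seq_len(nl)],
      species_branch = env$l_branch[seq_len(nl)],
      copy = env$l_copy[seq_len(nl)], stringsAsFactors = FALSE),
    founders = data.frame(
      founder_id = env$f_id[seq_len(nf)],
      copy = env$f_copy[seq_len(nf)], stringsAsFactors = FALSE),
    root_copy = root_copy$id
  )

  loci <- .simulate_genomes(config, genes)
  pairs <- .simulate_pairs(config, genes)
  seqs <- evolve_sequences(gt, n_codons = config$n_codons,
                           substitution_rate = config$substitution_rate,
                           omega = config$omega)

  structure(list(gene_tree = gt, genes = genes, loci = loci, pairs = pairs,
                 cds = seqs$cds, protein = seqs$protein, events = events,
                 species_tree = sp, clade_map = config$clade_map,
                 config = config),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("simulated_family:", nrow(x$genes), "genes in",
      length(unique(x$genes$species_id)), "species;",
      nrow(x$events$founders), "founders;",
      nrow(x$events$duplications), "duplications,",
      nrow(x$events$losses), "losses\n")
  invisible(x)
}

# newick for extant-pruned gene tree; unary internals are suppressed
.build_newick <- function(env) {
  n <- env$n_nodes
  kids <- vector("list", n)
  roots <- integer(0)
  for (i in seq_len(n)) {
    p <- env$parent[i]
    if (p == 0L) {
      if (env$type[i] != "loss") roots <- c(roots, i)
    } else {
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  build <- function(v, t_parent) {
    if (env$type[v] == "tip") {
      return(sprintf("%s:%g", env$label[v], env$time[v] - t_parent))
    }
    if (env$type[v] == "loss") return(NULL)
    parts <- Filter(Negate(is.null),
                    lapply(kids[[v]], build, t_parent = env$time[v]))
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) {
      # splice out the unary node, extending the child's branch
      return(.extend_branch(parts[[1L]], env$time[v] - t_parent))
    }
    sprintf("(%s):%g", paste(unlist(parts), collapse = ","),
            env$time[v] - t_parent)
  }
  built <- Filter(Negate(is.null),
                  lapply(roots, function(r) build(r, env$time[r])))
  stopifnot(length(built) >= 1L)
  str <- sub(":([0-9.eE+-]+)$", "", built[[1L]])
  paste0(if (!startsWith(str, "(")) paste0("(", str, ")") else str, ";")
}

.extend_branch <- function(part, extra) {
  m <- regmatches(part, regexec("^(.*):([0-9.eE+-]+)$", part))[[1]]
  sprintf("%s:%g", m[2], as.numeric(m[3]) + extra)
}

#' Simulate bootstrap-like supports
#'
#' Each internal node receives the full support value with probability
#' `q`, otherwise an integer drawn uniformly from `[30, 100)`.
#'
#' @param gt A `gene_tree`.
#' @param q Probability of full support per node.
#' @param full Support value assigned to confidently recovered nodes.
#' @return The `gene_tree` with its `support` vector filled.
#' @export
simulate_supports <- function(gt, q = 0.9, full = 100L) {
  n <- gt$phy$Nnode
  hi <- stats::runif(n) < q
  supp <- ifelse(hi, full,
                 30L + as.integer(floor(stats::runif(n) * 70)))
  gt$support <- as.integer(supp)
  gt$phy$node.label <- as.character(gt$support)
  gt
}

# per-species genomes: background gene slots + family insertions
.simulate_genomes <- function(config, genes) {
  out <- list()
  for (spx in config$synteny_species) {
    rows <- list()
    for (chr in seq_len(config$n_chrom)) {
      keep <- stats::runif(config$n_bg) >= config$p_relocate
      key <- seq_len(config$n_bg)
      chrom <- rep(chr, config$n_bg)
      if (any(!keep)) {  # relocated background genes break collinearity
        chrom[!keep] <- sample.int(config$n_chrom, sum(!keep), replace = TRUE)
        key[!keep] <- stats::runif(sum(!keep), 0, config$n_bg + 1)
      }
      rows[[chr]] <- data.frame(
        gene_id = sprintf("bg_%s_c%d_%03d", spx, chr, seq_len(config$n_bg)),
        slot = sprintf("slot_c%d_%03d", chr, seq_len(config$n_bg)),
        chrom = paste0("chr", chrom), key = key,
        stringsAsFactors = FALSE)
    }
    bg <- do.call(rbind, rows)
    fam <- genes[genes$species_id == spx, , drop = FALSE]
    all <- rbind(bg[, c("gene_id", "chrom", "key")],
                 data.frame(gene_id = fam$gene_id,
                            chrom = sprintf("chr%d", fam$chrom),
                            key = fam$key, stringsAsFactors = FALSE))
    all <- all[order(all$chrom, all$key), , drop = FALSE]
    pos <- stats::ave(seq_len(nrow(all)), all$chrom, FUN = seq_along)
    loci <- data.frame(gene_id = all$gene_id, chrom = all$chrom,
                       start = pos * 1000L, end = pos * 1000L + 500L,
                       strand = "+", stringsAsFactors = FALSE)
    out[[spx]] <- as_gene_loci(loci)
    attr(out[[spx]], "slots") <- stats::setNames(bg$slot, bg$gene_id)
  }
  out
}

# homolog pairs: family all-vs-all + background ortholog anchors between
# the synteny genomes (empty when no genomes are emitted)
.simulate_pairs <- function(config, genes) {
  if (length(config$synteny_species) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      evalue = numeric(0)))
  }
  fam <- genes$gene_id
  fam_pairs <- if (length(fam) >= 2L) {
    cmb <- utils::combn(fam, 2)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], evalue = 1e-50,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               evalue = numeric(0))
  }
  sps <- config$synteny_species
  bg_pairs <- list()
  if (length(sps) >= 2L) {
    slots <- as.vector(outer(sprintf("c%d", seq_len(config$n_chrom)),
                             sprintf("%03d", seq_len(config$n_bg)),
                             paste, sep = "_"))
    cmb <- utils::combn(sps, 2, simplify = FALSE)
    for (pr in cmb) {
      bg_pairs[[length(bg_pairs) + 1L]] <- data.frame(
        gene_a = paste0("bg_", pr[1], "_", slots),
        gene_b = paste0("bg_", pr[2], "_", slots),
        evalue = 1e-180, stringsAsFactors = FALSE)
    }
  }
  as_homolog_pairs(do.call(rbind, c(list(fam_pairs), bg_pairs)))
}

#' Evolve coding sequences along a gene tree
#'
#' A simple codon-level scheme: nucleotide mutation events arrive as a
#' Poisson process at `substitution_rate` per site; synonymous changes
#' are always accepted, nonsynonymous changes with probability `omega`
#' (for `omega > 1` synonymous acceptance is scaled by `1/omega`
#' instead), and changes creating stop codons are rejected, so no
#' internal stops arise.
#'
#' @param gt A `gene_tree` with branch lengths in time units.
#' @param n_codons Sequence length in codons.
#' @param substitution_rate Mutation rate per nucleotide site per time
#'   unit.
#' @param omega Nonsynonymous/synonymous acceptance ratio (>= 0).
#' @return List with `cds` ([Biostrings::DNAStringSet]) and `protein`
#'   ([Biostrings::AAStringSet]), named by gene id.
#' @export
evolve_sequences <- function(gt, n_codons = 300, substitution_rate = 0.012,
                             omega = 0.3) {
  if (omega < 0) stop("omega must be >= 0")
  phy <- gt$phy
  if (is.null(phy$edge.length)) stop("gene tree lacks branch lengths")
  gc <- .gencode()
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  p_non <- min(1, omega)
  p_syn <- if (omega > 1) 1 / omega else 1

  # integer codon machinery: codons indexed 1..64; trans[codon, site, k]
  # is the codon after replacing `site` with the k-th alternative base
  codons <- names(gc)
  aa <- unname(gc)
  cmat <- do.call(rbind, strsplit(codons, ""))
  trans <- array(0L, c(64L, 3L, 3L))
  for (ci in 1:64) for (p in 1:3) {
    alts <- setdiff(.NUC, cmat[ci, p])
    for (k in 1:3) {
      x <- cmat[ci, ]
      x[p] <- alts[k]
      trans[ci, p, k] <- match(paste(x, collapse = ""), codons)
    }
  }
  sense_idx <- which(aa != "*")

  seqs <- vector("list", ntip + phy$Nnode)
  seqs[[root]] <- sample(sense_idx, n_codons, replace = TRUE)
  ord <- rev(ape::postorder(phy))
  for (e in ord) {
    pe <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    s <- seqs[[pe]]
    t <- phy$edge.length[e]
    n_ev <- stats::rpois(1, substitution_rate * 3 * n_codons * t)
    if (n_ev > 0) {
      cod_i <- sample.int(n_codons, n_ev, replace = TRUE)
      off <- sample.int(3L, n_ev, replace = TRUE)
      alt <- sample.int(3L, n_ev, replace = TRUE)
      u_accept <- stats::runif(n_ev)
      for (k in seq_len(n_ev)) {
        old <- s[cod_i[k]]
        new <- trans[old, off[k], alt[k]]
        if (aa[new] == "*") next
        p_acc <- if (aa[new] == aa[old]) p_syn else p_non
        if (u_accept[k] <= p_acc) s[cod_i[k]] <- new
      }
    }
    seqs[[v]] <- s
  }
  cds_chr <- vapply(seq_len(ntip), function(i) {
    paste(codons[seqs[[i]]], collapse = "")
  }, character(1))
  ids <- gt$genes$gene_id[match(phy$tip.label, gt$genes$tip_label)]
  cds <- Biostrings::DNAStringSet(stats::setNames(cds_chr, ids))
  protein <- Biostrings::translate(cds)
  list(cds = cds, protein = protein)
}

#' Write a simulated family to plain-text files
#'
#' Emits `genetree.nwk`, `species.nwk`, `clades.tsv`, `genes.tsv`,
#' `loci_<species>.bed`, `pairs.tsv`, `cds.fasta`, `prot.fasta` and
#' `events.json` under `dir`.
#'
#' @param fam A `simulated_family`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_family <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_tree(fam$gene_tree, file.path(dir, "genetree.nwk"))
  ape::write.tree(fam$species_tree, file.path(dir, "species.nwk"))
  utils::write.table(
    data.frame(species_id = names(fam$clade_map),
               clade = unname(fam$clade_map)),
    file.path(dir, "clades.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(fam$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (spx in names(fam$loci)) {
    l <- fam$loci[[spx]]
    utils::write.table(
      data.frame(l$chrom, l$start, l$end, l$gene_id, 0L, l$strand),
      file.path(dir, sprintf("loci_%s.bed", spx)),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(fam$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(fam$cds, file.path(dir, "cds.fasta"))
  Biostrings::writeXStringSet(fam$protein, file.path(dir, "prot.fasta"))
  jsonlite::write_json(fam$events, file.path(dir, "events.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
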