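#' Collinearity chaining parameters
#'
#' Defaults follow the MCScanX-style parameterisation used for the
#' eight-genome synteny scan: 50 points per anchor, at least 10 anchors
#' per block, -1 per unit rank gap, a 5-rank overlap window, anchors
#' admitted at E-value 1e-10, and at most 25 intervening ranks between
#' consecutive anchors.
#'
#' @param match_score Score per chained anchor.
#' @param match_size Minimum anchors per reported block.
#' @param gap_penalty Penalty per unit rank gap (must be <= 0).
#' @param overlap_window Rank window for suppressing anchors near a
#'   higher-scoring block before re-chaining.
#' @param e_value_max Anchor admission threshold.
#' @param max_gaps Maximum intervening ranks between consecutive anchors.
#' @return A `chain_params` list.
#' @export
chain_params <- function(match_score = 50, match_size = 10,
                         gap_penalty = -1, overlap_window = 5,
                         e_value_max = 1e-10, max_gaps = 25) {
  if (match_size < 2) stop("match_size must be >= 2")
  if (max_gaps < 0) stop("max_gaps must be >= 0")
  if (gap_penalty > 0) stop("gap_penalty must be <= 0")
  structure(list(match_score = match_score, match_size = match_size,
                 gap_penalty = gap_penalty, overlap_window = overlap_window,
                 e_value_max = e_value_max, max_gaps = max_gaps),
            class = "chain_params")
}

#' Detect tandem homolog arrays from gene order
#'
#' Homologous genes (transitively, via the pair list) lying on the same
#' chromosome are grouped into arrays when consecutive members are within
#' `max_intervening` ranks of each other.  The event count of an array of
#' size k is k - 1 (each tandem duplication adds one member).
#'
#' @param loci Locus table from [read_gene_loci()]/[as_gene_loci()].
#' @param pairs Homolog pairs ([as_homolog_pairs()]).
#' @param max_intervening Maximum rank distance between consecutive array
#'   members.
#' @param e_value_max Pairs with larger E-value are ignored.
#' @return List with `arrays` (data.frame `array_id`, `chrom`,
#'   `gene_id`, `rank`), `n_arrays`, and `n_events` (sum of size-1
#'   over arrays).
#' @export
detect_tandem_arrays <- function(loci, pairs, max_intervening = 5,
                                 e_value_max = 1e-10) {
  pairs <- pairs[pairs$evalue <= e_value_max, , drop = FALSE]
  known <- pairs$gene_a %in% loci$gene_id & pairs$gene_b %in% loci$gene_id
  if (any(!known)) {
    warning(sum(!known), " homolog pairs reference genes without loci; skipped")
    pairs <- pairs[known, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    return(list(arrays = data.frame(array_id = integer(0),
                                    chrom = character(0),
                                    gene_id = character(0),
                                    rank = integer(0)),
                n_arrays = 0L, n_events = 0L))
  }
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = loci$gene_id)
  fam <- igraph::components(g)$membership
  loci$family <- fam[loci$gene_id]

  arrays <- list()
  aid <- 0L
  for (key in split(seq_len(nrow(loci)), paste(loci$family, loci$chrom))) {
    if (length(key) < 2L) next
    sub <- loci[key, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    brk <- c(0L, which(diff(sub$rank) > max_intervening), nrow(sub))
    for (i in seq_len(length(brk) - 1L)) {
      run <- (brk[i] + 1L):brk[i + 1L]
      if (length(run) < 2L) next
      aid <- aid + 1L
      arrays[[aid]] <- data.frame(array_id = aid,
                                  chrom = sub$chrom[run[1L]],
                                  gene_id = sub$gene_id[run],
                                  rank = sub$rank[run],
                                  stringsAsFactors = FALSE)
    }
  }
  arrays <- if (length(arrays) > 0L) do.call(rbind, arrays) else
    data.frame(array_id = integer(0), chrom = character(0),
               gene_id = character(0), rank = integer(0))
  sizes <- if (nrow(arrays) > 0L) table(arrays$array_id) else integer(0)
  list(arrays = arrays,
       n_arrays = length(sizes),
       n_events = sum(pmax(as.integer(sizes) - 1L, 0L)))
}

#' Chain collinear anchors on one chromosome pair
#'
#' Dynamic-programming chaining of homologous anchors into maximal-score
#' monotone blocks: `score(i) = match_score + max_j (score(j) +
#' gap_penalty * gap(i, j))` over predecessors `j` with both rank
#' increments in `[1, max_gaps + 1]` (the second genome's ranks
#' decreasing for inverted blocks), `gap(i, j) = (delta_rank_a - 1) +
#' (delta_rank_b - 1)`.  The best chain is extracted, anchors within
#' `overlap_window` ranks of its anchors are suppressed, and chaining
#' repeats until no block reaches `match_size` anchors.
#'
#' @param anchors data.frame with columns `gene_a`, `gene_b`, `rank_a`,
#'   `rank_b` (gene order ranks on the two chromosomes) and optional
#'   `evalue`.
#' @param params A [chain_params()] list.
#' @return List of `synteny_block`s, each a list with `anchors`
#'   (data.frame subset, chain order), `orientation` (`"same"` /
#'   `"inverted"`), `score`, `n_anchors`, `span_a`, `span_b`.
#' @export
chain_anchors <- function(anchors, params = chain_params()) {
  if (!is.null(anchors$evalue)) {
    anchors <- anchors[anchors$evalue <= params$e_value_max, , drop = FALSE]
  }
  if (nrow(anchors) == 0L) return(list())
  live <- rep(TRUE, nrow(anchors))
  blocks <- list()
  repeat {
    best <- NULL
    for (orient in c("same", "inverted")) {
      cand <- .best_chain(anchors[live, , drop = FALSE], params, orient)
      if (!is.null(cand) &&
          (is.null(best) || cand$score > best$score)) best <- cand
    }
    if (is.null(best) || best$n_anchors < params$match_size) break
    idx_live <- which(live)
    best_rows <- idx_live[best$rows]
    best$anchors <- anchors[best_rows, , drop = FALSE]
    best$rows <- NULL
    best$span_a <- range(best$anchors$rank_a)
    best$span_b <- range(best$anchors$rank_b)
    class(best) <- "synteny_block"
    blocks[[length(blocks) + 1L]] <- best
    # suppress anchors near the accepted block before re-chaining
    w <- params$overlap_window
    near <- vapply(seq_len(nrow(anchors)), function(i) {
      any(abs(anchors$rank_a[i] - best$anchors$rank_a) <= w &
          abs(anchors$rank_b[i] - best$anchors$rank_b) <= w)
    }, logical(1))
    live <- live & !near
    if (!any(live)) break
  }
  blocks
}

# single best-scoring chain under one orientation; rows are indices into
# the supplied anchor table
.best_chain <- function(anchors, params, orientation) {
  n <- nrow(anchors)
  if (n == 0L) return(NULL)
  rb <- if (orientation == "inverted") -anchors$rank_b else anchors$rank_b
  ord <- order(anchors$rank_a, rb)
  ra <- anchors$rank_a[ord]
  rb <- rb[ord]
  score <- rep(params$match_score, n)
  prev <- rep(NA_integer_, n)
  gmax <- params$max_gaps + 1
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- rb[i] - rb[j]
      if (da >= 1 && da <= gmax && db >= 1 && db <= gmax) {
        s <- params$match_score + score[j] +
          params$gap_penalty * ((da - 1) + (db - 1))
        if (s > score[i]) { score[i] <- s; prev[i] <- j }
      }
    }
  }
  top <- which.max(score)
  chain <- top
  while (!is.na(prev[chain[1L]])) chain <- c(prev[chain[1L]], chain)
  list(rows = ord[chain], orientation = orientation,
       score = score[top], n_anchors = length(chain))
}

#' Chain anchors across all chromosome pairs of two genomes
#'
#' @param loci_a,loci_b Locus tables for the two genomes (may be the same
#'   table for an intragenome scan).
#' @param pairs Homolog pairs with genes in the two tables.
#' @param params A [chain_params()].
#' @return data.frame of blocks (`block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, `score`, rank spans) with the block
#'   objects attached as attribute `"blocks"`.
#' @export
chain_genome_pair <- function(loci_a, loci_b, pairs,
                              params = chain_params()) {
  ia <- match(pairs$gene_a, loci_a$gene_id)
  ib <- match(pairs$gene_b, loci_b$gene_id)
  swap <- is.na(ia)
  if (any(swap)) {  # pair stored the other way round
    ia[swap] <- match(pairs$gene_b[swap], loci_a$gene_id)
    ib[swap] <- match(pairs$gene_a[swap], loci_b$gene_id)
    tmp <- pairs$gene_a[swap]
    pairs$gene_a[swap] <- pairs$gene_b[swap]
    pairs$gene_b[swap] <- tmp
  }
  ok <- !is.na(ia) & !is.na(ib)
  pairs <- pairs[ok, , drop = FALSE]
  anc <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    chrom_a = loci_a$chrom[ia[ok]], chrom_b = loci_b$chrom[ib[ok]],
    rank_a = loci_a$rank[ia[ok]], rank_b = loci_b$rank[ib[ok]],
    evalue = pairs$evalue, stringsAsFactors = FALSE
  )
  rows <- list()
  objs <- list()
  bid <- 0L
  for (grp in split(seq_len(nrow(anc)), paste(anc$chrom_a, anc$chrom_b))) {
    bl <- chain_anchors(anc[grp, , drop = FALSE], params)
    for (b in bl) {
      bid <- bid + 1L
      rows[[bid]] <- data.frame(
        block_id = bid,
        chrom_a = b$anchors$chrom_a[1L], chrom_b = b$anchors$chrom_b[1L],
        orientation = b$orientation, n_anchors = b$n_anchors,
        score = b$score,
        start_a = b$span_a[1L], end_a = b$span_a[2L],
        start_b = b$span_b[1L], end_b = b$span_b[2L],
        stringsAsFactors = FALSE
      )
      objs[[bid]] <- b
    }
  }
  out <- if (bid > 0L) do.call(rbind, rows) else
    data.frame(block_id = integer(0), chrom_a = character(0),
               chrom_b = character(0), orientation = character(0),
               n_anchors = integer(0), score = numeric(0),
               start_a = integer(0), end_a = integer(0),
               start_b = integer(0), end_b = integer(0))
  attr(out, "blocks") <- objs
  out
}

#' Classify interspecific homolog pairs as syntenic or dispersed
#'
#' A pair is syntenic when both genes are anchors of (or, optionally,
#' fall within the rank span of) one shared collinear block between
#' their chromosomes.  Within-species tandem counts sit on the diagonal
#' of the returned matrix, syntenic / nonsyntenic interspecific pair
#' counts off the diagonal.
#'
#' @param partition A `lineage_partition` (supplies gene -> species and
#'   gene -> lineage).
#' @param pairs Homolog pairs among family genes.
#' @param loci Named list of locus tables, one per species.
#' @param params A [chain_params()].
#' @param span_membership Count a pair whose genes merely lie inside a
#'   block's rank spans (not necessarily as anchors) as syntenic.
#' @param tandem_max_intervening Passed to [detect_tandem_arrays()].
#' @param genome_pairs Optional homolog pairs (incl. non-family anchors)
#'   used for block construction; defaults to `pairs`.
#' @return A `synteny_matrix`: list with `pair_class` (data.frame per
#'   interspecific pair: genes, species, lineage, `syntenic`,
#'   `as_anchor`), `n_syntenic`, `n_nonsyntenic`, `n_lineages_syntenic`,
#'   `tandem` (per-species event counts), `matrix` (species x species).
#' @export
classify_pairs <- function(partition, pairs, loci, params = chain_params(),
                           span_membership = TRUE,
                           tandem_max_intervening = 5,
                           genome_pairs = NULL) {
  asg <- partition$assignment
  sp_of <- stats::setNames(asg$species_id, asg$gene_id)
  lin_of <- stats::setNames(asg$lineage_id, asg$gene_id)
  species <- names(loci)
  if (is.null(species)) stop("`loci` must be a named list (names = species)")
  if (is.null(genome_pairs)) genome_pairs <- pairs

  gene_species <- function(g) unname(sp_of[g])
  pairs$sp_a <- gene_species(pairs$gene_a)
  pairs$sp_b <- gene_species(pairs$gene_b)
  unmapped <- is.na(pairs$sp_a) | is.na(pairs$sp_b)
  if (any(unmapped)) {
    warning(sum(unmapped), " pairs with genes outside the partition; excluded")
    pairs <- pairs[!unmapped, , drop = FALSE]
  }
  covered <- pairs$sp_a %in% species & pairs$sp_b %in% species
  if (any(!covered)) {
    warning(sum(!covered), " pairs span genomes without loci; excluded")
    pairs <- pairs[covered, , drop = FALSE]
  }

  inter <- pairs[pairs$sp_a != pairs$sp_b, , drop = FALSE]

  # blocks per unordered species pair
  blocks <- list()
  combos <- utils::combn(sort(species), 2, simplify = FALSE)
  for (cmb in combos) {
    key <- paste(cmb, collapse = "\r")
    gp <- genome_pairs
    # genome-wide anchors may include genes outside the family/partition,
    # so membership is decided by the locus tables (gene ids are unique
    # per genome)
    in_a1 <- gp$gene_a %in% loci[[cmb[1]]]$gene_id
    in_b1 <- gp$gene_b %in% loci[[cmb[1]]]$gene_id
    in_a2 <- gp$gene_a %in% loci[[cmb[2]]]$gene_id
    in_b2 <- gp$gene_b %in% loci[[cmb[2]]]$gene_id
    use <- (in_a1 & in_b2) | (in_a2 & in_b1)
    blocks[[key]] <- chain_genome_pair(loci[[cmb[1]]], loci[[cmb[2]]],
                                       gp[use, , drop = FALSE], params)
  }

  inter$syntenic <- logical(nrow(inter))
  inter$as_anchor <- logical(nrow(inter))
  if (nrow(inter) > 0L) {
    # orient every pair as (first species of the sorted pair, second)
    swap <- inter$sp_a > inter$sp_b
    if (any(swap)) {
      tmp <- inter$gene_a[swap]
      inter$gene_a[swap] <- inter$gene_b[swap]
      inter$gene_b[swap] <- tmp
      tmp <- inter$sp_a[swap]
      inter$sp_a[swap] <- inter$sp_b[swap]
      inter$sp_b[swap] <- tmp
    }
    grp <- paste(inter$sp_a, inter$sp_b, sep = "\r")
    for (key in unique(grp)) {
      rows <- which(grp == key)
      cmb <- strsplit(key, "\r", fixed = TRUE)[[1]]
      tab <- blocks[[key]]
      if (is.null(tab) || nrow(tab) == 0L) next
      objs <- attr(tab, "blocks")
      la <- loci[[cmb[1]]]; lb <- loci[[cmb[2]]]
      ia <- match(inter$gene_a[rows], la$gene_id)
      ib <- match(inter$gene_b[rows], lb$gene_id)
      ra <- la$rank[ia]; ca <- la$chrom[ia]
      rb <- lb$rank[ib]; cb <- lb$chrom[ib]
      pair_key <- paste(inter$gene_a[rows], inter$gene_b[rows], sep = "\r")
      anchor_hit <- rep(FALSE, length(rows))
      span_hit <- rep(FALSE, length(rows))
      for (b in objs) {
        bca <- b$anchors$chrom_a[1L]; bcb <- b$anchors$chrom_b[1L]
        on_chr <- !is.na(ra) & !is.na(rb) & ca == bca & cb == bcb
        if (!any(on_chr)) next
        anchor_hit <- anchor_hit | (on_chr & pair_key %in%
          paste(b$anchors$gene_a, b$anchors$gene_b, sep = "\r"))
        span_hit <- span_hit | (on_chr &
          ra >= b$span_a[1L] & ra <= b$span_a[2L] &
          rb >= b$span_b[1L] & rb <= b$span_b[2L])
      }
      inter$syntenic[rows] <- anchor_hit |
        (span_membership & span_hit)
      inter$as_anchor[rows] <- anchor_hit
    }
  }
  inter$lineage_a <- unname(lin_of[inter$gene_a])
  inter$lineage_b <- unname(lin_of[inter$gene_b])

  # within-species tandem events
  tandem <- stats::setNames(integer(length(species)), species)
  for (sp in species) {
    intra <- pairs[pairs$sp_a == sp & pairs$sp_b == sp, , drop = FALSE]
    ta <- detect_tandem_arrays(loci[[sp]], intra,
                               max_intervening = tandem_max_intervening,
                               e_value_max = params$e_value_max)
    tandem[sp] <- ta$n_events
  }

  m_syn <- matrix(0L, length(species), length(species),
                  dimnames = list(species, species))
  m_non <- m_syn
  if (nrow(inter) > 0L) {
    for (i in seq_len(nrow(inter))) {
      a <- inter$sp_a[i]; b <- inter$sp_b[i]
      if (inter$syntenic[i]) {
        m_syn[a, b] <- m_syn[a, b] + 1L; m_syn[b, a] <- m_syn[b, a] + 1L
      } else {
        m_non[a, b] <- m_non[a, b] + 1L; m_non[b, a] <- m_non[b, a] + 1L
      }
    }
  }
  diag(m_syn) <- tandem

  syn_lin <- unique(c(inter$lineage_a[inter$syntenic],
                      inter$lineage_b[inter$syntenic]))
  structure(list(
    pair_class = inter,
    n_syntenic = sum(inter$syntenic),
    n_nonsyntenic = sum(!inter$syntenic),
    n_syntenic_anchor_only = sum(inter$as_anchor),
    n_lineages_syntenic = length(syn_lin),
    tandem = tandem,
    n_tandem_events = sum(tandem),
    matrix_syntenic = m_syn,
    matrix_nonsyntenic = m_non,
    blocks = blocks
  ), class = "synteny_matrix")
}

#' @export
print.synteny_matrix <- function(x, ...) {
  cat("synteny_matrix:", x$n_syntenic, "syntenic /", x$n_nonsyntenic,
      "nonsyntenic interspecific pairs;", x$n_tandem_events,
      "tandem duplication events\n")
  invisible(x)
}
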