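#' LCA reconciliation of a gene tree with a species tree
#'
#' Each gene-tree node is mapped to the species-tree last common ancestor
#' of its descendant species.  An internal node is labelled a duplication
#' when the mappings of at least two of its children are not in disjoint
#' species-tree subtrees (one is ancestral to or equal to the other);
#' otherwise it is a speciation.
#'
#' @param gt A `gene_tree`.
#' @param sp_tree Rooted species tree ([ape::phylo]); its leaf set must
#'   contain every species in the gene tree.
#' @return A `node_reconciliation`: data.frame with one row per gene-tree
#'   node: `node`, `species_node` (species-tree node id),
#'   `species_label`, `event` (`"leaf"`, `"speciation"`,
#'   `"duplication"`).
#' @export
lca_reconcile <- function(gt, sp_tree) {
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  tip_sp <- gt$genes$species_id[match(phy$tip.label, gt$genes$tip_label)]
  sp_idx <- match(tip_sp, sp_tree$tip.label)
  if (anyNA(sp_idx)) {
    stop("species absent from the species tree: ",
         paste(unique(tip_sp[is.na(sp_idx)]), collapse = ", "))
  }
  spar <- .parent_vec(sp_tree)
  sdepth <- .node_depths(sp_tree)

  map <- integer(ntip + phy$Nnode)
  map[seq_len(ntip)] <- sp_idx
  event <- rep("leaf", ntip + phy$Nnode)
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]
    if (map[p] == 0L) {
      kids <- .children_of(phy, p)
      m <- map[kids[1L]]
      for (k in kids[-1L]) m <- .lca2(spar, sdepth, m, map[k])
      map[p] <- m
      dup <- FALSE
      for (i in seq_along(kids)) {
        for (j in seq_along(kids)) {
          if (i < j) {
            a <- map[kids[i]]; b <- map[kids[j]]
            if (.is_anc_or_equal(spar, a, b) || .is_anc_or_equal(spar, b, a)) {
              dup <- TRUE
            }
          }
        }
      }
      event[p] <- if (dup) "duplication" else "speciation"
    }
  }
  labels <- c(sp_tree$tip.label,
              if (is.null(sp_tree$node.label)) rep("", sp_tree$Nnode)
              else sp_tree$node.label)
  structure(data.frame(
    node = seq_len(ntip + phy$Nnode),
    species_node = map,
    species_label = labels[map],
    event = event,
    stringsAsFactors = FALSE
  ), class = c("node_reconciliation", "data.frame"),
     sp_tree = sp_tree, gene_tree = gt)
}

# gene-tree nodes that lie wholly inside one lineage (all descendant
# leaves belong to it), per lineage
.nodes_inside_lineage <- function(gt, partition) {
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  lin <- partition$assignment$lineage_id[
    match(phy$tip.label, partition$assignment$tip_label)]
  ids <- unique(lin)
  # a node is inside lineage i iff all its descendant leaves are
  all_in <- matrix(TRUE, ntip + phy$Nnode, length(ids))
  all_in[seq_len(ntip), ] <- FALSE
  all_in[cbind(seq_len(ntip), match(lin, ids))] <- TRUE
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; k <- phy$edge[e, 2]
    all_in[p, ] <- all_in[p, ] & all_in[k, ]
  }
  colnames(all_in) <- ids
  all_in
}

.check_same_tree <- function(rec, partition) {
  gt <- attr(rec, "gene_tree")
  if (!identical(sort(gt$phy$tip.label),
                 sort(partition$tree$phy$tip.label))) {
    stop("partition and reconciliation come from different gene trees")
  }
}

#' Per-lineage copy number at a named ancestor
#'
#' A lineage is present at an ancestor when at least one of its member
#' species descends from that ancestor; its copy count there is 1 plus
#' the number of duplication nodes inside the lineage whose LCA mapping
#' is at or above the ancestor.
#'
#' @param rec A `node_reconciliation` from [lca_reconcile()].
#' @param partition A `lineage_partition` built from the same gene tree.
#' @param ancestor_name Name of a species-tree node (tip or internal
#'   label, e.g. `"LCA_ABD"`).
#' @return List with `per_lineage` (named integer vector, `NA` for absent
#'   lineages) and `total`.
#' @export
copy_number_at <- function(rec, partition, ancestor_name) {
  .check_same_tree(rec, partition)
  sp_tree <- attr(rec, "sp_tree")
  gt <- attr(rec, "gene_tree")
  anc <- species_node(sp_tree, ancestor_name)
  spar <- .parent_vec(sp_tree)
  anc_species <- sp_tree$tip.label[.tips_under(sp_tree, anc)]

  inside <- .nodes_inside_lineage(gt, partition)
  ntip <- length(gt$phy$tip.label)
  is_dup <- rec$event == "duplication"
  at_or_above <- vapply(rec$species_node, function(m) {
    .is_anc_or_equal(spar, m, anc)
  }, logical(1))

  ids <- colnames(inside)
  per <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (i in seq_along(ids)) {
    rows <- partition$assignment$lineage_id == ids[i]
    present <- any(partition$assignment$species_id[rows] %in% anc_species)
    if (!present) next
    internal <- seq_len(nrow(rec)) > ntip
    per[i] <- 1L + sum(is_dup & at_or_above & inside[, i] & internal)
  }
  list(per_lineage = per, total = sum(per, na.rm = TRUE))
}

#' Tally copy-number gains and losses between ancestral nodes
#'
#' Gains: one founding duplication per ingroup lineage beyond the first
#' (the expansion from a single ancestral copy to one copy per lineage in
#' the ingroup ancestor), plus within-lineage duplication nodes mapped at
#' or above a clade ancestor with at least one descendant gene from that
#' ancestor's clade.  Losses (Dollo-style): one per (lineage, clade) pair
#' where an ingroup lineage contains no gene from that clade.  Both a
#' pooled gain tally (each duplication node counted once) and a per-clade
#' tally (a node counted toward every clade ancestor it predates) are
#' reported.
#'
#' @inheritParams copy_number_at
#' @param clade_map Named character vector species -> clade.
#' @param ancestors Named character vector mapping clade labels to
#'   species-tree ancestor names, e.g.
#'   `c(A = "LCA_A", B = "LCA_B", D = "LCA_D")`.
#' @return A `gain_loss_summary`: list with `gains_total`,
#'   `gains_founding`, `gains_per_clade`, `gains_pooled_dups`,
#'   `losses_total`, `loss_pairs` (data.frame lineage x clade),
#'   `per_lineage` breakdown.
#' @export
tally_gains_losses <- function(rec, partition, clade_map,
                               ancestors = c(A = "LCA_A", B = "LCA_B",
                                             D = "LCA_D")) {
  .check_same_tree(rec, partition)
  sp_tree <- attr(rec, "sp_tree")
  gt <- attr(rec, "gene_tree")
  spar <- .parent_vec(sp_tree)
  ntip <- length(gt$phy$tip.label)

  ing <- partition$lineages[!partition$lineages$is_outgroup, , drop = FALSE]
  gains_founding <- max(nrow(ing) - 1L, 0L)

  inside <- .nodes_inside_lineage(gt, partition)
  is_dup <- rec$event == "duplication"
  internal <- seq_len(nrow(rec)) > ntip

  # clade content per gene-tree node (over the clade roles in `ancestors`)
  asg <- partition$assignment
  tip_clade <- asg$clade[match(gt$phy$tip.label, asg$tip_label)]
  has_clade <- matrix(FALSE, nrow(rec), length(ancestors),
                      dimnames = list(NULL, names(ancestors)))
  hit <- tip_clade %in% names(ancestors)
  has_clade[cbind(which(hit), match(tip_clade[hit], names(ancestors)))] <- TRUE
  for (e in ape::postorder(gt$phy)) {
    p <- gt$phy$edge[e, 1]; k <- gt$phy$edge[e, 2]
    has_clade[p, ] <- has_clade[p, ] | has_clade[k, ]
  }

  per_clade <- stats::setNames(integer(length(ancestors)), names(ancestors))
  qual_any <- rep(FALSE, nrow(rec))
  per_lineage_gain <- stats::setNames(integer(nrow(ing)), ing$lineage_id)
  per_lineage_gain_nodes <- list()
  for (cl in names(ancestors)) {
    anc <- species_node(sp_tree, ancestors[[cl]])
    at_or_above <- vapply(rec$species_node, function(m) {
      .is_anc_or_equal(spar, m, anc)
    }, logical(1))
    qual <- is_dup & internal & at_or_above & has_clade[, cl] &
      rowSums(inside[, ing$lineage_id, drop = FALSE]) > 0
    per_clade[cl] <- sum(qual)
    qual_any <- qual_any | qual
  }
  for (i in seq_len(nrow(ing))) {
    nodes <- which(qual_any & inside[, ing$lineage_id[i]])
    per_lineage_gain[i] <- length(nodes)
    per_lineage_gain_nodes[[ing$lineage_id[i]]] <- nodes
  }
  gains_pooled_dups <- sum(qual_any)

  # Dollo losses: ingroup lineage x clade absences
  loss_pairs <- expand.grid(lineage_id = ing$lineage_id,
                            clade = names(ancestors),
                            stringsAsFactors = FALSE)
  loss_pairs$lost <- vapply(seq_len(nrow(loss_pairs)), function(r) {
    rows <- asg$lineage_id == loss_pairs$lineage_id[r]
    !any(asg$clade[rows] == loss_pairs$clade[r])
  }, logical(1))
  loss_pairs <- loss_pairs[loss_pairs$lost, c("lineage_id", "clade"),
                           drop = FALSE]
  rownames(loss_pairs) <- NULL

  structure(list(
    gains_founding = gains_founding,
    gains_per_clade = per_clade,
    gains_pooled_dups = gains_pooled_dups,
    gains_total = gains_founding + gains_pooled_dups,
    gains_total_per_clade = gains_founding + sum(per_clade),
    losses_total = nrow(loss_pairs),
    loss_pairs = loss_pairs,
    per_lineage_gains = per_lineage_gain,
    per_lineage_gain_nodes = per_lineage_gain_nodes,
    ancestors = ancestors
  ), class = "gain_loss_summary")
}

#' @export
print.gain_loss_summary <- function(x, ...) {
  cat("gain_loss_summary: gains", x$gains_total,
      "(", x$gains_founding, "founding +", x$gains_pooled_dups,
      "within-lineage );", "losses", x$losses_total, "\n")
  cat("per-clade duplication gains:",
      paste(names(x$gains_per_clade), x$gains_per_clade, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
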