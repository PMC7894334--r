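#' Clade content of a gene-tree node
#'
#' The set of species-clade labels represented among the leaves under a
#' node.
#'
#' @param gt A `gene_tree`.
#' @param node Integer node id (tip or internal).
#' @param clade_map Named character vector species -> clade
#'   (see [as_clade_map()]).
#' @return Character vector of clade labels (sorted, unique).
#' @export
clade_content <- function(gt, node, clade_map) {
  tips <- .tips_under(gt$phy, node)
  sp <- gt$genes$species_id[match(gt$phy$tip.label[tips], gt$genes$tip_label)]
  .species_clades(sp, clade_map)
}

.species_clades <- function(species, clade_map) {
  miss <- setdiff(unique(species), names(clade_map))
  if (length(miss) > 0L) {
    stop("species missing from clade map: ", paste(miss, collapse = ", "))
  }
  sort(unique(unname(clade_map[species])))
}

#' Ancestral-lineage membership criterion 1
#'
#' A clade qualifies when it contains genes from the deep-branching
#' ingroup clade (default `D`) together with genes from at least one of
#' the crown clades (default `A`, `B`) -- i.e. it spans the ingroup root
#' and is therefore interpretable as descending from a single gene in the
#' ingroup ancestor.
#'
#' @inheritParams clade_content
#' @param crown_clades Clade labels of which at least one must be present.
#' @param deep_clade Clade label that must be present.
#' @return Logical.
#' @export
satisfies_criterion1 <- function(gt, node, clade_map,
                                 crown_clades = c("A", "B"),
                                 deep_clade = "D") {
  cc <- clade_content(gt, node, clade_map)
  (deep_clade %in% cc) && length(intersect(crown_clades, cc)) > 0L
}

#' Ancestral-lineage membership criterion 2
#'
#' A clade qualifies when its sister clade satisfies
#' [satisfies_criterion1()].  The root (which has no sister) never
#' qualifies.
#'
#' @inheritParams satisfies_criterion1
#' @return Logical.
#' @export
satisfies_criterion2 <- function(gt, node, clade_map,
                                 crown_clades = c("A", "B"),
                                 deep_clade = "D") {
  phy <- gt$phy
  par <- .parent_vec(phy)
  if (par[node] == 0L) return(FALSE)
  sisters <- setdiff(.children_of(phy, par[node]), node)
  any(vapply(sisters, function(s) {
    satisfies_criterion1(gt, s, clade_map, crown_clades, deep_clade)
  }, logical(1)))
}

#' Partition a gene tree into ancestral homolog lineages
#'
#' Walks the rooted gene tree top-down and anchors a lineage at every
#' minimal well-supported clade that either spans the ingroup root
#' (criterion 1: contains the deep clade `D` plus at least one of the
#' crown clades `A`/`B`) or is sister to such a clade (criterion 2).
#' A clade is minimal when its leaf set cannot be exactly partitioned
#' into two or more smaller qualifying well-supported clades.  All
#' outgroup-clade leaves form one additional lineage.  Ingroup leaves
#' falling under no qualifying clade are absorbed into the topologically
#' nearest anchored lineage (configurable).
#'
#' @param gt A rooted `gene_tree` with the outgroup clade on one side of
#'   the root (see [root_by_outgroup()]).
#' @param clade_map Named character vector species -> clade.
#' @param support_min Minimum internal-node support for a clade to count
#'   as well supported (bootstrap percent).
#' @param outgroup_clade Clade label whose genes form the outgroup
#'   lineage; `NA` for no outgroup.
#' @param crown_clades,deep_clade Clade roles for the two criteria.
#' @param support_absent `"fail"` (default): nodes without a support value
#'   fail the support test; `"pass"`: they pass.  Leaves always pass
#'   (terminal branches carry no bootstrap).
#' @param unassigned_policy `"nearest_anchor"` (default) absorbs stray
#'   ingroup leaves into the anchored lineage sharing the most recent
#'   ancestor; `"own_lineage"` gives each maximal stray clade its own
#'   lineage.
#' @return A `lineage_partition`: list with `assignment` (one row per
#'   gene: `gene_id`, `species_id`, `clade`, `lineage_id`, `anchor_node`,
#'   `anchor_support`, `absorbed`), `lineages` (per-lineage summary),
#'   and the parameters used.
#' @export
delineate_lineages <- function(gt, clade_map, support_min = 60,
                               outgroup_clade = "F",
                               crown_clades = c("A", "B"),
                               deep_clade = "D",
                               support_absent = c("fail", "pass"),
                               unassigned_policy = c("nearest_anchor",
                                                     "own_lineage")) {
  support_absent <- match.arg(support_absent)
  unassigned_policy <- match.arg(unassigned_policy)
  phy <- gt$phy
  if (!ape::is.rooted(phy)) stop("gene tree must be rooted; see root_by_outgroup()")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  par <- .parent_vec(phy)

  tip_sp <- gt$genes$species_id[match(phy$tip.label, gt$genes$tip_label)]
  .species_clades(tip_sp, clade_map)  # validates coverage
  tip_clade <- unname(clade_map[tip_sp])

  if (all(is.na(gt$support)) && support_absent == "fail") {
    stop("all internal supports are absent; set support_absent = \"pass\" ",
         "or supply a supported tree")
  }

  # clade-content incidence, nodes x clade levels, by postorder sweep
  levels <- sort(unique(unname(clade_map)))
  content <- matrix(FALSE, ntip + phy$Nnode, length(levels),
                    dimnames = list(NULL, levels))
  content[cbind(seq_len(ntip), match(tip_clade, levels))] <- TRUE
  for (e in ape::postorder(phy)) {
    content[phy$edge[e, 1], ] <- content[phy$edge[e, 1], ] | content[phy$edge[e, 2], ]
  }

  crit1 <- function(v) {
    content[v, deep_clade] && any(content[v, intersect(crown_clades, levels)])
  }
  crit2 <- function(v) {
    if (par[v] == 0L) return(FALSE)
    any(vapply(setdiff(.children_of(phy, par[v]), v), crit1, logical(1)))
  }

  # outgroup side of the root
  og_tips <- which(tip_clade == outgroup_clade %||% "")
  root_kids <- .children_of(phy, root)
  ingroup_root <- root
  if (length(og_tips) > 0L) {
    og_kids <- root_kids[vapply(root_kids, function(k) {
      all(.tips_under(phy, k) %in% og_tips)
    }, logical(1))]
    covered_og <- sort(unlist(lapply(og_kids, .tips_under, phy = phy)))
    if (!identical(covered_og, sort(og_tips))) {
      stop("outgroup-clade genes do not form one side of the root; ",
           "root the tree with root_by_outgroup() first")
    }
    in_kids <- setdiff(root_kids, og_kids)
    if (length(in_kids) == 1L) ingroup_root <- in_kids
  }

  sup_ok <- function(v) {
    if (v <= ntip) return(TRUE)
    if (v == ingroup_root || v == root) return(TRUE)  # whole-ingroup fallback
    s <- gt$support[v - ntip]
    if (is.na(s)) return(support_absent == "pass")
    s >= support_min
  }
  qualifies <- function(v) sup_ok(v) && (crit1(v) || crit2(v))

  # covered(v): leaves(v) admits an exact partition into qualifying clades
  covered <- rep(FALSE, ntip + phy$Nnode)
  for (v in seq_len(ntip)) covered[v] <- qualifies(v)
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]
    kids <- .children_of(phy, p)
    covered[p] <- qualifies(p) || all(covered[kids])
  }

  anchors <- integer(0)
  in_outgroup <- if (length(og_tips) > 0L) {
    function(v) all(.tips_under(phy, v) %in% og_tips)
  } else {
    function(v) FALSE
  }
  walk <- function(v) {
    if (in_outgroup(v)) return(invisible())
    kids <- .children_of(phy, v)
    divisible <- length(kids) > 0L && all(covered[kids])
    if (qualifies(v) && !divisible) {
      anchors <<- c(anchors, v)
    } else if (length(kids) > 0L) {
      for (k in kids) walk(k)
    }
  }
  start <- if (ingroup_root == root) root else ingroup_root
  walk(start)

  warned_single <- FALSE
  if (length(anchors) == 0L) {
    ingroup_tips <- setdiff(seq_len(ntip), og_tips)
    if (length(ingroup_tips) > 0L) {
      warning("no clade satisfies either criterion; ",
              "emitting a single ingroup lineage")
      warned_single <- TRUE
      anchors <- if (ingroup_root != root) ingroup_root else root
    }
  }

  # preorder lineage numbering (cladewise = parent-before-child, left
  # to right in input child order)
  pre <- c(root, ape::reorder.phylo(phy, "cladewise")$edge[, 2])
  anchors <- anchors[order(match(anchors, pre))]
  depth <- .node_depths(phy)

  assign_lin <- rep(NA_integer_, ntip)
  absorbed <- rep(FALSE, ntip)
  anchor_of <- rep(NA_integer_, ntip)
  for (i in seq_along(anchors)) {
    tips <- .tips_under(phy, anchors[i])
    assign_lin[tips] <- i
    anchor_of[tips] <- anchors[i]
  }

  # strays: ingroup leaves under no anchor
  strays <- setdiff(which(is.na(assign_lin)), og_tips)
  if (length(strays) > 0L && length(anchors) > 0L) {
    if (unassigned_policy == "nearest_anchor") {
      anchor_tip_depth <- depth[anchors]
      for (leaf in strays) {
        u <- par[leaf]
        hit <- integer(0)
        while (u != 0L && length(hit) == 0L) {
          hit <- anchors[vapply(anchors, function(a) .is_anc_or_equal(par, u, a),
                                logical(1))]
          u <- par[u]
        }
        if (length(hit) == 0L) hit <- anchors
        pick <- hit[order(depth[hit], hit)][1L]  # shallowest, then node id
        i <- match(pick, anchors)
        assign_lin[leaf] <- i
        anchor_of[leaf] <- pick
        absorbed[leaf] <- TRUE
      }
    } else {
      # each maximal stray clade becomes its own lineage
      stray_set <- strays
      repeat {
        if (length(stray_set) == 0L) break
        leaf <- stray_set[1L]
        v <- leaf
        while (par[v] != 0L &&
               all(.tips_under(phy, par[v]) %in% strays)) v <- par[v]
        i <- length(anchors) + 1L
        anchors <- c(anchors, v)
        tips <- .tips_under(phy, v)
        assign_lin[tips] <- i
        anchor_of[tips] <- v
        stray_set <- setdiff(stray_set, tips)
      }
    }
  }

  n_in <- max(c(assign_lin, 0L), na.rm = TRUE)
  if (length(og_tips) > 0L) {
    assign_lin[og_tips] <- n_in + 1L
    og_anchor <- if (ingroup_root != root) {
      setdiff(root_kids, ingroup_root)[1L]
    } else {
      NA_integer_
    }
    anchor_of[og_tips] <- og_anchor
  }

  lin_ids <- paste0("L", assign_lin)
  sup_at <- function(v) {
    if (is.na(v) || v <= ntip) NA_integer_ else gt$support[v - ntip]
  }
  assignment <- data.frame(
    tip_label = phy$tip.label,
    gene_id = gt$genes$gene_id[match(phy$tip.label, gt$genes$tip_label)],
    species_id = tip_sp,
    clade = tip_clade,
    lineage_id = lin_ids,
    anchor_node = anchor_of,
    anchor_support = vapply(anchor_of, sup_at, integer(1)),
    absorbed = absorbed,
    stringsAsFactors = FALSE
  )
  total <- max(assign_lin)
  lineages <- do.call(rbind, lapply(seq_len(total), function(i) {
    rows <- assignment[assign_lin == i, , drop = FALSE]
    data.frame(
      lineage_id = paste0("L", i),
      anchor_node = rows$anchor_node[1L],
      n_members = nrow(rows),
      n_species = length(unique(rows$species_id)),
      clades = paste(sort(unique(rows$clade)), collapse = ","),
      anchor_support = rows$anchor_support[1L],
      is_outgroup = length(og_tips) > 0L && i == total,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(
    assignment = assignment,
    lineages = lineages,
    support_min = support_min,
    outgroup_clade = outgroup_clade,
    support_absent = support_absent,
    unassigned_policy = unassigned_policy,
    single_lineage_fallback = warned_single,
    tree = gt
  ), class = "lineage_partition")
}

#' @export
print.lineage_partition <- function(x, ...) {
  cat("lineage_partition:", nrow(x$lineages), "lineages over",
      nrow(x$assignment), "genes (support_min =", x$support_min, ")\n")
  print(x$lineages, row.names = FALSE)
  invisible(x)
}

#' Write a lineage partition as TSV
#'
#' One row per gene: `gene_id`, `species_id`, `clade`, `lineage_id`,
#' `anchor_node_id`, `anchor_support`.
#'
#' @param partition A `lineage_partition`.
#' @param file Output path.
#' @export
write_lineage_partition <- function(partition, file) {
  out <- partition$assignment[, c("gene_id", "species_id", "clade",
                                  "lineage_id", "anchor_node",
                                  "anchor_support")]
  names(out)[5] <- "anchor_node_id"
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
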