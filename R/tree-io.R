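#' Read a gene tree with bootstrap-like supports
#'
#' Parses a newick string or file into a `gene_tree` object.  Internal node
#' labels are interpreted, when numeric, as support values (ultrafast
#' bootstrap percentages by default).  Tip labels are split into a gene
#' identifier and a species identifier.
#'
#' @param x A newick string, or path to a file containing one tree.
#' @param support_scale `"percent"` (labels already in 0--100) or
#'   `"fraction"` (labels in 0--1, multiplied by 100 on ingest).
#' @param label_pattern Regular expression with two capture groups applied
#'   to every tip label; group 1 is the gene id, group 2 the species id.
#'   The default splits at the first underscore or pipe.
#' @return A `gene_tree`: a list with elements `phy` (an [ape::phylo]),
#'   `genes` (data.frame `tip_label`, `gene_id`, `species_id`) and
#'   `support` (integer vector of length `phy$Nnode`, `NA` where a node
#'   carries no support).
#' @examples
#' gt <- read_gene_tree("((g1_spA:1,g2_spB:1)95:1,g3_spD:1);")
#' gt$support
#' @export
read_gene_tree <- function(x, support_scale = c("percent", "fraction"),
                           label_pattern = "^([^_|]+)[_|](.+)$") {
  support_scale <- match.arg(support_scale)
  txt <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  .check_newick_syntax(txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed newick: parser failed on input")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate leaf names: ", paste(dup, collapse = ", "))
  }
  m <- regmatches(phy$tip.label, regexec(label_pattern, phy$tip.label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("tip labels not matching label_pattern: ",
         paste(utils::head(phy$tip.label[bad], 5L), collapse = ", "))
  }
  genes <- data.frame(
    tip_label  = phy$tip.label,
    gene_id    = vapply(m, `[`, "", 2L),
    species_id = vapply(m, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  gt <- structure(list(phy = phy, genes = genes), class = "gene_tree")
  gt$support <- .parse_supports(phy, support_scale)
  gt
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree:", length(x$phy$tip.label), "genes from",
      length(unique(x$genes$species_id)), "species;",
      sum(!is.na(x$support)), "supported internal nodes\n")
  invisible(x)
}

# Balanced-parenthesis scan so malformed input reports a character offset.
.check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed newick: unbalanced ')' at character offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed newick: ", depth, " unclosed '(' at character offset ",
         length(chars))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("malformed newick: missing ';' terminator at character offset ",
         nchar(txt))
  }
  invisible(TRUE)
}

.parse_supports <- function(phy, support_scale) {
  supp <- rep(NA_integer_, phy$Nnode)
  lab <- phy$node.label
  if (is.null(lab)) return(supp)
  num <- suppressWarnings(as.numeric(lab))
  ok <- !is.na(num) & nzchar(lab)
  if (support_scale == "fraction") num <- num * 100
  supp[ok] <- as.integer(round(num[ok]))
  if (any(supp < 0L | supp > 100L, na.rm = TRUE)) {
    stop("support values outside [0, 100] after scaling")
  }
  supp
}

#' Write a gene tree to newick
#'
#' Supports are emitted as internal node labels (`)95:0.1` style); nodes
#' without support get an empty label.
#'
#' @param gt A `gene_tree`.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return The newick string, invisibly when writing to a file.
#' @export
write_gene_tree <- function(gt, file = NULL) {
  phy <- gt$phy
  lab <- ifelse(is.na(gt$support), "", as.character(gt$support))
  phy$node.label <- lab
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root a gene tree on the edge separating an outgroup from the ingroup
#'
#' @param gt A `gene_tree`.
#' @param outgroup Character vector of tip labels (or gene ids) forming the
#'   outgroup.
#' @return The rooted `gene_tree`; leaf set unchanged, supports preserved
#'   as edge-associated values.
#' @export
root_by_outgroup <- function(gt, outgroup) {
  phy <- gt$phy
  tips <- .resolve_tips(gt, outgroup)
  if (length(tips) == 0L) stop("empty outgroup")
  if (length(tips) == length(phy$tip.label)) {
    stop("outgroup cannot contain every leaf")
  }
  if (ape::is.rooted(phy)) {
    root <- length(phy$tip.label) + 1L
    kids <- phy$edge[phy$edge[, 1] == root, 2]
    for (k in kids) {
      under <- phy$tip.label[.tips_under(phy, k)]
      if (setequal(under, tips)) return(gt)  # already rooted as requested
    }
    phy <- ape::unroot(phy)
  }
  if (!ape::is.monophyletic(phy, tips)) {
    viol <- .outgroup_violators(phy, tips)
    stop("outgroup is not monophyletic in the unrooted tree; ",
         "intruding leaves: ", paste(viol, collapse = ", "))
  }
  lab <- ifelse(is.na(gt$support), "", as.character(gt$support))
  phy$node.label <- lab[seq_len(phy$Nnode)]
  rphy <- ape::root(phy, outgroup = tips, resolve.root = TRUE,
                    edgelabel = TRUE)
  out <- gt
  out$phy <- rphy
  out$support <- .parse_supports(rphy, "percent")
  out
}

# Leaves that break outgroup monophyly: root away from the outgroup and
# list non-outgroup tips under the outgroup MRCA.
.outgroup_violators <- function(phy, tips) {
  other <- setdiff(phy$tip.label, tips)
  r <- ape::root(phy, outgroup = other[1], resolve.root = TRUE)
  mrca <- ape::getMRCA(r, tips)
  under <- r$tip.label[.tips_under(r, mrca)]
  setdiff(under, tips)
}

.resolve_tips <- function(gt, ids) {
  hit <- ids %in% gt$phy$tip.label
  out <- ids
  out[!hit] <- gt$genes$tip_label[match(ids[!hit], gt$genes$gene_id)]
  if (anyNA(out)) {
    stop("unknown leaves: ", paste(ids[is.na(out)], collapse = ", "))
  }
  out
}

#' Last common ancestor of a set of nodes
#'
#' @param gt A `gene_tree`, or a bare [ape::phylo].
#' @param nodes Tip labels and/or integer node ids.
#' @return Integer node id of the lowest node ancestral to (or equal to)
#'   every input node.
#' @export
lca <- function(gt, nodes) {
  phy <- if (inherits(gt, "gene_tree")) gt$phy else gt
  if (length(nodes) == 0L) stop("lca of an empty node set is undefined")
  if (is.character(nodes)) {
    ids <- match(nodes, phy$tip.label)
    if (anyNA(ids)) {
      stop("unknown tips: ", paste(nodes[is.na(ids)], collapse = ", "))
    }
    nodes <- ids
  }
  tipsets <- lapply(nodes, function(n) {
    if (n <= length(phy$tip.label)) n else .tips_under(phy, n)
  })
  tips <- unique(unlist(tipsets))
  if (length(tips) == 1L) {
    # single leaf: its own lca unless the query named an internal node
    return(if (length(nodes) == 1L) nodes[[1]] else tips)
  }
  ape::getMRCA(phy, tips)
}

#' Read a species tree with named ancestors
#'
#' Internal node labels (e.g. `LCA_Brassicaceae`, `LCA_ABD`, `LCA_A`) name
#' ancestors referenced by the reconciliation stage.
#'
#' @param x Newick string or file path.
#' @return An [ape::phylo] with `node.label` carrying ancestor names.
#' @export
read_species_tree <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  .check_newick_syntax(txt)
  phy <- ape::read.tree(text = txt)
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  phy
}

#' Resolve a named species-tree node
#'
#' @param sp_tree Species tree ([ape::phylo]) with named internal nodes.
#' @param name A tip label or internal node label.
#' @return Integer node id.
#' @export
species_node <- function(sp_tree, name) {
  i <- match(name, sp_tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(name, sp_tree$node.label)
  if (is.na(j)) stop("unknown species-tree node name: ", name)
  length(sp_tree$tip.label) + j
}
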