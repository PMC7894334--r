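# Shared low-level tree helpers.  All take an ape::phylo and use ape's
# node numbering (tips 1..n, internals n+1..n+Nnode, root = n+1).

.tips_under <- function(phy, node) {
  if (node <= length(phy$tip.label)) return(node)
  phangorn::Descendants(phy, node, type = "tips")[[1]]
}

.parent_vec <- function(phy) {
  par <- integer(length(phy$tip.label) + phy$Nnode)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par  # 0 for the root
}

.children_of <- function(phy, node) phy$edge[phy$edge[, 1] == node, 2]

.node_depths <- function(phy) {
  par <- .parent_vec(phy)
  depth <- rep(NA_integer_, length(par))
  root <- length(phy$tip.label) + 1L
  depth[root] <- 0L
  ord <- rev(ape::postorder(phy))  # edges ordered parent before child
  for (e in ord) {
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + 1L
  }
  depth
}

# Is node `a` an ancestor of (or equal to) node `b`?
.is_anc_or_equal <- function(par, a, b) {
  v <- b
  repeat {
    if (v == a) return(TRUE)
    v <- par[v]
    if (v == 0L) return(FALSE)
  }
}

# LCA of two nodes via parent walks (small trees; used on species trees).
.lca2 <- function(par, depth, a, b) {
  while (depth[a] > depth[b]) a <- par[a]
  while (depth[b] > depth[a]) b <- par[b]
  while (a != b) { a <- par[a]; b <- par[b] }
  a
}
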