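# Independent brute-force oracles and random-input generators shared by
# the unit and acceptance tests.  Everything here deliberately avoids the
# package's own code paths for the quantity it checks.

# random gene tree over a small A/B/D species pool; supports uniform
rand_gene_tree <- function(n_leaves, species_pool = NULL, support = NULL) {
  if (is.null(species_pool)) {
    species_pool <- c("spA1", "spA2", "spA3", "spB1", "spB2",
                      "spD1", "spD2")
  }
  phy <- ape::rtree(n_leaves, br = 1)
  sp <- sample(species_pool, n_leaves, replace = TRUE)
  phy$tip.label <- sprintf("g%d_%s", seq_len(n_leaves), sp)
  if (is.null(support)) support <- sample(30:100, phy$Nnode, replace = TRUE)
  phy$node.label <- as.character(support)
  read_gene_tree(ape::write.tree(phy))
}

pool_clade_map <- function() {
  as_clade_map(c(spA1 = "A", spA2 = "A", spA3 = "A",
                 spB1 = "B", spB2 = "B",
                 spD1 = "D", spD2 = "D", spF1 = "F"))
}

# parent vector straight from the edge matrix
oracle_parents <- function(phy) {
  par <- integer(length(phy$tip.label) + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) par[phy$edge[i, 2]] <- phy$edge[i, 1]
  par
}

# path-intersection LCA: intersect root paths, take the deepest node
oracle_lca <- function(phy, tips) {
  par <- oracle_parents(phy)
  root_path <- function(v) {
    p <- v
    while (par[v] != 0L) { v <- par[v]; p <- c(p, v) }
    p
  }
  paths <- lapply(tips, root_path)
  common <- Reduce(intersect, paths)
  common[1L]  # paths are ordered leaf -> root, so first common is deepest
}

# leaf sets under every node, from scratch
oracle_leafsets <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  par <- oracle_parents(phy)
  sets <- lapply(seq_len(n), function(i) integer(0))
  for (tip in seq_along(phy$tip.label)) {
    v <- tip
    repeat {
      sets[[v]] <- c(sets[[v]], tip)
      if (par[v] == 0L) break
      v <- par[v]
    }
  }
  lapply(sets, sort)
}

# criteria recomputed from leaf sets only
oracle_crit1 <- function(leafset, tip_clades) {
  cl <- unique(tip_clades[leafset])
  ("D" %in% cl) && any(c("A", "B") %in% cl)
}

# exhaustive clade-cover lineage oracle: top-down over nodes, with
# divisibility decided by exact-cover search over qualifying leaf sets
oracle_delineate <- function(gt, clade_map, support_min = 60) {
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  par <- oracle_parents(phy)
  sets <- oracle_leafsets(phy)
  sp <- gt$genes$species_id[match(phy$tip.label, gt$genes$tip_label)]
  tip_clades <- unname(clade_map[sp])

  crit1 <- function(v) oracle_crit1(sets[[v]], tip_clades)
  crit2 <- function(v) {
    if (par[v] == 0L) return(FALSE)
    sibs <- setdiff(which(par == par[v]), v)
    any(vapply(sibs, crit1, logical(1)))
  }
  sup_ok <- function(v) {
    if (v <= ntip || v == root) return(TRUE)
    as.integer(gt$support[v - ntip]) >= support_min
  }
  qual_nodes <- which(vapply(seq_along(sets), function(v) {
    sup_ok(v) && (crit1(v) || crit2(v))
  }, logical(1)))
  qual_sets <- sets[qual_nodes]

  # exact cover of leaf set S by >= min_parts qualifying clades
  coverable <- function(S, min_parts) {
    if (length(S) == 0L) return(min_parts <= 0L)
    pivot <- S[1L]
    for (k in seq_along(qual_sets)) {
      C <- qual_sets[[k]]
      if (pivot %in% C && all(C %in% S)) {
        if (coverable(setdiff(S, C), min_parts - 1L)) return(TRUE)
      }
    }
    FALSE
  }
  anchors <- integer(0)
  walk <- function(v) {
    q <- sup_ok(v) && (crit1(v) || crit2(v))
    # divisibility: exact cover by >= 2 qualifying clades strictly below v
    divisible <- length(sets[[v]]) > 1L && {
      inner <- qual_sets[vapply(qual_sets, function(C) {
        all(C %in% sets[[v]]) && length(C) < length(sets[[v]])
      }, logical(1))]
      old <- qual_sets
      qual_sets <<- inner
      ans <- coverable(sets[[v]], 2L)
      qual_sets <<- old
      ans
    }
    if (q && !divisible) {
      anchors <<- c(anchors, v)
    } else if (v > ntip) {
      for (k in which(par == v)) walk(k)
    }
  }
  walk(root)
  lapply(sort(anchors), function(v) sets[[v]])
}

# all monotone chains over an anchor table, by explicit enumeration
oracle_best_chain_score <- function(anchors, params) {
  n <- nrow(anchors)
  best <- -Inf
  gmax <- params$max_gaps + 1
  score_chain <- function(idx, rb_sign) {
    ra <- anchors$rank_a[idx]
    rb <- rb_sign * anchors$rank_b[idx]
    if (length(idx) > 1L) {
      da <- diff(ra); db <- diff(rb)
      if (any(da < 1 | da > gmax | db < 1 | db > gmax)) return(-Inf)
      gaps <- sum(da - 1) + sum(db - 1)
    } else gaps <- 0
    params$match_score * length(idx) + params$gap_penalty * gaps
  }
  extend <- function(idx, rb_sign) {
    s <- score_chain(idx, rb_sign)
    if (is.finite(s) && s > best) best <<- s
    last <- idx[length(idx)]
    for (k in seq_len(n)) {
      if (anchors$rank_a[k] > anchors$rank_a[last]) {
        s2 <- score_chain(c(idx, k), rb_sign)
        if (is.finite(s2)) extend(c(idx, k), rb_sign)
      }
    }
  }
  for (sgn in c(1, -1)) {
    for (start in seq_len(n)) extend(start, sgn)
  }
  best
}

# NG86 counting re-derived from scratch (sites + pathway averaging)
oracle_ng86 <- function(cds_a, cds_b) {
  gc <- Biostrings::GENETIC_CODE
  nuc <- c("A", "C", "G", "T")
  codons_a <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  codons_b <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  syn_sites <- function(cod) {
    s <- 0
    ch <- strsplit(cod, "")[[1]]
    for (p in 1:3) for (alt in setdiff(nuc, ch[p])) {
      x <- ch; x[p] <- alt
      xa <- gc[[paste(x, collapse = "")]]
      if (xa != "*" && xa == gc[[cod]]) s <- s + 1/3
    }
    s
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(r) c(v[i], r))
    }))
  }
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(codons_a)) {
    ca <- codons_a[i]; cb <- codons_b[i]
    si <- (syn_sites(ca) + syn_sites(cb)) / 2
    S <- S + si; N <- N + 3 - si
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(pos) == 0) next
    res <- matrix(NA_real_, 0, 2)
    for (ordp in perms(pos)) {
      cur <- strsplit(ca, "")[[1]]
      tgt <- strsplit(cb, "")[[1]]
      sd <- nd <- 0; ok <- TRUE
      for (p in ordp) {
        nxt <- cur; nxt[p] <- tgt[p]
        if (gc[[paste(nxt, collapse = "")]] == "*") { ok <- FALSE; break }
        if (gc[[paste(cur, collapse = "")]] ==
            gc[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res <- rbind(res, c(sd, nd))
    }
    if (nrow(res) == 0) {  # all pathways stop-blocked: average everything
      for (ordp in perms(pos)) {
        cur <- strsplit(ca, "")[[1]]
        tgt <- strsplit(cb, "")[[1]]
        sd <- nd <- 0
        for (p in ordp) {
          nxt <- cur; nxt[p] <- tgt[p]
          if (gc[[paste(cur, collapse = "")]] ==
              gc[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        res <- rbind(res, c(sd, nd))
      }
    }
    Sd <- Sd + mean(res[, 1]); Nd <- Nd + mean(res[, 2])
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# mutate a CDS with k random single-nucleotide changes, avoiding stops
mutate_cds <- function(cds, k) {
  gc <- Biostrings::GENETIC_CODE
  nuc <- c("A", "C", "G", "T")
  s <- strsplit(cds, "")[[1]]
  done <- 0
  while (done < k) {
    p <- sample(length(s), 1)
    old <- s[p]
    s2 <- s
    s2[p] <- sample(setdiff(nuc, old), 1)
    cod_i <- (p - 1) %/% 3 + 1
    cod <- paste(s2[(cod_i * 3 - 2):(cod_i * 3)], collapse = "")
    if (gc[[cod]] == "*") next
    s <- s2
    done <- done + 1
  }
  paste(s, collapse = "")
}

# replay the simulator's event log: copies alive at a species tip
replay_alive <- function(fam, species) {
  sp <- fam$species_tree
  labels <- c(sp$tip.label, sp$node.label)
  par <- oracle_parents(sp)
  v <- match(species, sp$tip.label)
  path_labels <- character(0)
  while (v != 0L && par[v] != 0L) {
    path_labels <- c(path_labels, labels[v])
    v <- par[v]
  }
  alive <- fam$events$root_copy
  ev <- rbind(
    if (nrow(fam$events$duplications) > 0)
      data.frame(time = fam$events$duplications$time,
                 branch = fam$events$duplications$species_branch,
                 what = "dup",
                 copy = fam$events$duplications$new_copy,
                 stringsAsFactors = FALSE),
    if (nrow(fam$events$losses) > 0)
      data.frame(time = fam$events$losses$time,
                 branch = fam$events$losses$species_branch,
                 what = "loss",
                 copy = fam$events$losses$copy,
                 stringsAsFactors = FALSE))
  if (!is.null(ev) && nrow(ev) > 0) {
    ev <- ev[ev$branch %in% path_labels, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      if (ev$what[i] == "dup") alive <- c(alive, ev$copy[i])
      else alive <- setdiff(alive, ev$copy[i])
    }
  }
  sort(alive)
}

# true per-clade early-duplication tally from the event log (losses = 0)
true_gains_per_clade <- function(fam, ancestors = c(A = "LCA_A",
                                                    B = "LCA_B",
                                                    D = "LCA_D"),
                                 founder_node = "LCA_ABD") {
  sp <- fam$species_tree
  labels <- c(sp$tip.label, sp$node.label)
  par <- oracle_parents(sp)
  anc_or_eq <- function(a, b) {  # is a ancestor-or-equal of b
    v <- b
    repeat {
      if (v == a) return(TRUE)
      if (par[v] == 0L) return(FALSE)
      v <- par[v]
    }
  }
  fnode <- match(founder_node, labels)
  out <- stats::setNames(integer(length(ancestors)), names(ancestors))
  d <- fam$events$duplications
  for (cl in names(ancestors)) {
    target <- match(ancestors[[cl]], labels)
    cnt <- 0L
    for (i in seq_len(nrow(d))) {
      b <- match(d$species_branch[i], labels)
      if (b != fnode && anc_or_eq(fnode, b) && anc_or_eq(b, target)) {
        cnt <- cnt + 1L
      }
    }
    out[cl] <- cnt
  }
  out
}
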