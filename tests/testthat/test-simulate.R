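two_species_config <- function(seed, lambda = 0, mu = 0, ...) {
  sp <- ape::read.tree(text = "(x:1,y:1)R;")
  sim_config(species_tree = sp, clade_map = c(x = "A", y = "B"),
             lambda = lambda, mu = mu, lambda_sigma = 0, stem_boost = 1,
             n_chrom = 1, n_bg = 10, n_codons = 3,
             substitution_rate = 0, seed = seed, ...)
}

test_that("without events the gene tree is congruent to the species tree", {
  fam <- simulate_family(sim_config(seed = 1, lambda = 0, mu = 0,
                                    lambda_sigma = 0, stem_boost = 1,
                                    n_codons = 3, substitution_rate = 0))
  expect_equal(nrow(fam$genes),
               length(fam$species_tree$tip.label))  # one gene per species
  expect_equal(sort(fam$genes$species_id), sort(fam$species_tree$tip.label))
  g <- fam$gene_tree$phy
  g$tip.label <- fam$genes$species_id[match(
    g$tip.label, fam$gene_tree$genes$tip_label)]
  expect_equal(phangorn::RF.dist(ape::unroot(g),
                                 ape::unroot(fam$species_tree)), 0)
  expect_equal(nrow(fam$events$duplications), 0L)
  expect_equal(nrow(fam$events$losses), 0L)
})

test_that("pure-birth copy numbers match the exponential expectation", {
  counts <- integer(0)
  for (s in 1:300) {
    fam <- simulate_family(two_species_config(seed = s, lambda = 0.1))
    counts <- c(counts, as.integer(table(fam$genes$species_id)))
  }
  m <- mean(counts)
  want <- exp(0.1)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - want), 3 * se + 1e-9)
})

test_that("the same seed reproduces byte-identical outputs", {
  f1 <- simulate_family(sim_config(seed = 99, n_codons = 30))
  f2 <- simulate_family(sim_config(seed = 99, n_codons = 30))
  expect_identical(write_gene_tree(f1$gene_tree),
                   write_gene_tree(f2$gene_tree))
  expect_identical(as.character(f1$cds), as.character(f2$cds))
  expect_identical(f1$pairs, f2$pairs)
  expect_identical(f1$loci, f2$loci)
  expect_identical(f1$events$duplications, f2$events$duplications)
  f3 <- simulate_family(sim_config(seed = 100, n_codons = 30))
  expect_false(identical(write_gene_tree(f1$gene_tree),
                         write_gene_tree(f3$gene_tree)))
})

test_that("simulated supports follow the two-component model", {
  set.seed(131)
  phy <- ape::rtree(2001)
  phy$tip.label <- sprintf("g%d_spA1", seq_len(2001))
  gt <- read_gene_tree(ape::write.tree(phy))
  g1 <- simulate_supports(gt, q = 1)
  expect_true(all(g1$support == 100L))
  set.seed(7)
  ga <- simulate_supports(gt, q = 0.5)
  set.seed(7)
  gb <- simulate_supports(gt, q = 0.5)
  expect_identical(ga$support, gb$support)
  # mixture weight: share of full supports is binomial around q
  n <- length(ga$support)
  expect_lt(abs(mean(ga$support == 100L) - 0.5), 3 * sqrt(0.25 / n))
  # the continuous component is uniform on [30, 100)
  lows <- ga$support[ga$support != 100L]
  h <- table(cut(lows, breaks = seq(30, 100, by = 10)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
})

test_that("zero branch lengths leave sequences identical", {
  gt <- read_gene_tree("(a_x:0,b_y:0);")
  seqs <- evolve_sequences(gt, n_codons = 50, substitution_rate = 0.1)
  expect_identical(as.character(seqs$cds[["a"]]),
                   as.character(seqs$cds[["b"]]))
  expect_false(any(grepl("\\*", as.character(seqs$protein))))
})

test_that("tandem placements are adjacent in the emitted genomes", {
  fam <- simulate_family(sim_config(seed = 5, n_codons = 3,
                                    substitution_rate = 0))
  d <- fam$events$duplications
  tand <- d[d$placement == "tandem", , drop = FALSE]
  genes <- fam$genes
  dists <- integer(0)
  for (i in seq_len(nrow(tand))) {
    # the duplicate key sits within 1e-6 of its parent: in any genome
    # containing both copies they occupy adjacent ranks, except where a
    # later tandem duplicate of the same parent interleaves
    kids <- genes[genes$copy_id == tand$new_copy[i], , drop = FALSE]
    for (j in seq_len(nrow(kids))) {
      spx <- kids$species_id[j]
      if (!spx %in% names(fam$loci)) next
      par_gene <- genes[genes$copy_id == tand$parent_copy[i] &
                          genes$species_id == spx, , drop = FALSE]
      if (nrow(par_gene) != 1) next
      l <- fam$loci[[spx]]
      r1 <- l$rank[l$gene_id == kids$gene_id[j]]
      r2 <- l$rank[l$gene_id == par_gene$gene_id]
      dists <- c(dists, abs(r1 - r2))
    }
  }
  # nested tandem duplications form arrays, so a minority of parent-child
  # pairs are separated by sibling duplicates; direct adjacency dominates
  expect_gt(length(dists), 0)
  expect_equal(as.numeric(stats::median(dists)), 1)
  expect_gt(mean(dists <= 3), 0.7)
})

test_that("default-regime family sizes span the expected order", {
  sizes <- integer(0)
  for (s in c(1, 4, 10)) {
    fam <- simulate_family(sim_config(seed = s, n_codons = 3,
                                      substitution_rate = 0))
    sizes <- c(sizes, as.integer(table(fam$genes$species_id)))
  }
  expect_gte(max(sizes), 15L)   # expanded genomes reach dozens of copies
  expect_lte(min(sizes), 10L)   # contracted genomes keep a handful
  expect_lte(max(sizes), 300L)
})

test_that("a refused configuration names the cause", {
  expect_error(sim_config(lambda = -1), "rates")
  expect_error(sim_config(p_tandem = 2), "p_tandem")
  sp <- ape::read.tree(text = "(x:100,y:100)R;")
  expect_error(
    simulate_family(sim_config(species_tree = sp,
                               clade_map = c(x = "A", y = "B"),
                               lambda = 0.2, lambda_sigma = 0,
                               stem_boost = 1, seed = 1)),
    "10\\^4")
})
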