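mk_loci <- function(chrom, ranks, prefix = "g") {
  # ranks are genuine gene-order positions: pad the chromosome with
  # filler genes so rank gaps correspond to real intervening genes
  fill <- setdiff(seq_len(max(ranks) + 2), ranks)
  as_gene_loci(data.frame(
    gene_id = c(sprintf("%s%d", prefix, seq_along(ranks)),
                sprintf("fill%s%d", prefix, seq_along(fill))),
    chrom = chrom,
    start = c(ranks, fill) * 1000, end = c(ranks, fill) * 1000 + 500,
    strand = "+", stringsAsFactors = FALSE))
}

test_that("tandem arrays follow the consecutive-rank-distance rule", {
  # two adjacent homologs -> one array of two
  loci <- mk_loci("c1", c(7, 8))
  pairs <- as_homolog_pairs(data.frame(gene_a = "g1", gene_b = "g2",
                                       evalue = 1e-20))
  ta <- detect_tandem_arrays(loci, pairs)
  expect_equal(ta$n_arrays, 1L)
  expect_equal(ta$n_events, 1L)

  # ranks 1, 3, 20 with bound 5: array {1,3} plus a distant singleton
  loci2 <- mk_loci("c1", c(1, 3, 20))
  pairs2 <- as_homolog_pairs(data.frame(
    gene_a = c("g1", "g1", "g2"), gene_b = c("g2", "g3", "g3"),
    evalue = 1e-20))
  ta2 <- detect_tandem_arrays(loci2, pairs2, max_intervening = 5)
  expect_equal(ta2$n_arrays, 1L)
  expect_setequal(ta2$arrays$gene_id, c("g1", "g2"))

  # chains extend transitively through consecutive members
  loci3 <- mk_loci("c1", c(1, 4, 8))
  ta3 <- detect_tandem_arrays(loci3, pairs2, max_intervening = 5)
  expect_equal(ta3$n_arrays, 1L)
  expect_equal(ta3$n_events, 2L)

  # arrays are invariant under rank translation and id relabeling
  loci4 <- mk_loci("c9", c(1, 4, 8) + 57, prefix = "x")
  pairs4 <- as_homolog_pairs(data.frame(
    gene_a = c("x1", "x1", "x2"), gene_b = c("x2", "x3", "x3"),
    evalue = 1e-20))
  ta4 <- detect_tandem_arrays(loci4, pairs4, max_intervening = 5)
  expect_equal(ta4$n_events, ta3$n_events)
})

test_that("genes in the pair list but absent from loci are skipped", {
  loci <- mk_loci("c1", c(1, 2))
  pairs <- as_homolog_pairs(data.frame(
    gene_a = c("g1", "g1"), gene_b = c("g2", "ghost"), evalue = 1e-20))
  expect_warning(ta <- detect_tandem_arrays(loci, pairs), "skipped")
  expect_equal(ta$n_arrays, 1L)
})

test_that("a perfectly collinear run chains into one full-score block", {
  anchors <- data.frame(gene_a = sprintf("a%d", 1:12),
                        gene_b = sprintf("b%d", 1:12),
                        rank_a = 1:12, rank_b = 1:12, evalue = 1e-50)
  bl <- chain_anchors(anchors, chain_params())
  expect_length(bl, 1L)
  expect_equal(bl[[1]]$n_anchors, 12L)
  expect_equal(bl[[1]]$score, 600)
  expect_equal(bl[[1]]$orientation, "same")

  inv <- anchors
  inv$rank_b <- 13 - inv$rank_a
  bli <- chain_anchors(inv, chain_params(match_size = 10))
  expect_length(bli, 1L)
  expect_equal(bli[[1]]$orientation, "inverted")
  expect_equal(bli[[1]]$score, 600)
})

test_that("gap penalties and the rank-gap bound shape block scores", {
  # one missing rank on each side costs gap_penalty per unit
  anchors <- data.frame(gene_a = sprintf("a%d", 1:10),
                        gene_b = sprintf("b%d", 1:10),
                        rank_a = c(1:5, 7:11), rank_b = c(1:5, 7:11),
                        evalue = 1e-50)
  bl <- chain_anchors(anchors, chain_params())
  expect_equal(bl[[1]]$score, 10 * 50 - 2)
  # a gap beyond max_gaps splits the run below match_size
  far <- anchors
  far$rank_a[6:10] <- far$rank_a[6:10] + 40
  far$rank_b[6:10] <- far$rank_b[6:10] + 40
  expect_length(chain_anchors(far, chain_params()), 0L)
  expect_length(chain_anchors(far, chain_params(match_size = 5)), 2L)
})

test_that("DP chaining equals exhaustive enumeration on small layouts", {
  set.seed(71)
  params <- chain_params(match_size = 2, max_gaps = 4)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    anchors <- data.frame(
      gene_a = sprintf("a%d", seq_len(n)),
      gene_b = sprintf("b%d", seq_len(n)),
      rank_a = sample(1:12, n),
      rank_b = sample(1:12, n),
      evalue = 1e-50)
    want <- oracle_best_chain_score(anchors, params)
    got_same <- linfam:::.best_chain(anchors, params, "same")
    got_inv <- linfam:::.best_chain(anchors, params, "inverted")
    expect_equal(max(got_same$score, got_inv$score), want)
  }
})

test_that("planted collinear segments are classified as syntenic", {
  set.seed(81)
  # two genomes sharing a 12-anchor collinear segment on c1; family genes
  # fx1/fy1 sit inside the segment span, fx2/fy2 lie far away on c2
  bg_a <- data.frame(gene_id = sprintf("ax%d", 1:20), chrom = "c1",
                     start = (1:20) * 1000, end = (1:20) * 1000 + 500,
                     strand = "+")
  bg_b <- data.frame(gene_id = sprintf("bx%d", 1:20), chrom = "c1",
                     start = (1:20) * 1000, end = (1:20) * 1000 + 500,
                     strand = "+")
  fam_a <- data.frame(gene_id = c("fx1", "fx2"), chrom = c("c1", "c2"),
                      start = c(5500, 100), end = c(5600, 200),
                      strand = "+")
  fam_b <- data.frame(gene_id = c("fy1", "fy2"), chrom = c("c1", "c2"),
                      start = c(5500, 900), end = c(5600, 950),
                      strand = "+")
  loci <- list(sp1 = as_gene_loci(rbind(bg_a, fam_a)),
               sp2 = as_gene_loci(rbind(bg_b, fam_b)))
  anchor_pairs <- data.frame(gene_a = sprintf("ax%d", 1:12),
                             gene_b = sprintf("bx%d", 1:12),
                             evalue = 1e-60)
  fam_pairs <- data.frame(gene_a = c("fx1", "fx2"),
                          gene_b = c("fy1", "fy2"), evalue = 1e-60)
  partition <- structure(list(
    assignment = data.frame(
      tip_label = c("fx1_sp1", "fx2_sp1", "fy1_sp2", "fy2_sp2"),
      gene_id = c("fx1", "fx2", "fy1", "fy2"),
      species_id = c("sp1", "sp1", "sp2", "sp2"),
      clade = "A", lineage_id = c("L1", "L2", "L1", "L2"),
      anchor_node = NA, anchor_support = NA, absorbed = FALSE,
      stringsAsFactors = FALSE),
    lineages = data.frame(lineage_id = c("L1", "L2"), is_outgroup = FALSE)
  ), class = "lineage_partition")
  sm <- classify_pairs(partition, as_homolog_pairs(fam_pairs), loci,
                       genome_pairs = as_homolog_pairs(
                         rbind(anchor_pairs, fam_pairs)))
  cls <- sm$pair_class
  expect_true(cls$syntenic[cls$gene_a == "fx1"])
  expect_false(cls$syntenic[cls$gene_a == "fx2"])
  expect_equal(sm$n_syntenic, 1L)
  expect_equal(sm$n_nonsyntenic, 1L)
  expect_equal(sm$n_lineages_syntenic, 1L)
  # no blocks -> everything nonsyntenic
  sm0 <- classify_pairs(partition, as_homolog_pairs(fam_pairs), loci,
                        genome_pairs = as_homolog_pairs(fam_pairs))
  expect_equal(sm0$n_syntenic, 0L)
})

test_that("classification is symmetric in genome order", {
  fam <- simulate_family(sim_config(seed = 4, n_codons = 30,
                                    substitution_rate = 0))
  p <- delineate_lineages(fam$gene_tree, fam$clade_map)
  sm1 <- suppressWarnings(classify_pairs(p, fam$pairs, fam$loci))
  sm2 <- suppressWarnings(classify_pairs(p, fam$pairs, rev(fam$loci)))
  expect_equal(sm1$n_syntenic, sm2$n_syntenic)
  expect_equal(sm1$n_nonsyntenic, sm2$n_nonsyntenic)
  expect_equal(sm1$n_tandem_events, sm2$n_tandem_events)
})
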