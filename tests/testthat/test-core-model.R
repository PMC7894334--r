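test_that("newick parsing extracts genes, species and supports", {
  gt <- read_gene_tree("((g1_A.thaliana:1,g2_B.rapa:1)95:1,g3_A.alpina:1);")
  expect_equal(nrow(gt$genes), 3L)
  expect_equal(gt$genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(gt$genes$species_id, c("A.thaliana", "B.rapa", "A.alpina"))
  expect_equal(sort(gt$support), 95L)  # one labelled node, root unlabelled
  # fractional supports are rescaled on ingest
  gtf <- read_gene_tree("((a_x:1,b_y:1)0.97:1,c_z:1);",
                        support_scale = "fraction")
  expect_equal(sort(gtf$support), 97L)
})

test_that("malformed newick reports a character offset; duplicates named", {
  expect_error(read_gene_tree("((a_x:1,b_y:1):1,c_z:1"), "offset")
  expect_error(read_gene_tree("(a_x:1,b_y:1)):1;"), "offset 14")
  expect_error(read_gene_tree("((a_x:1,a_x:1):1,c_z:1);"), "a_x")
})

test_that("write/read round trip preserves topology, supports, lengths", {
  set.seed(7)
  for (i in 1:10) {
    gt <- rand_gene_tree(sample(5:20, 1))
    gt2 <- read_gene_tree(write_gene_tree(gt))
    expect_equal(gt2$support, gt$support)
    expect_equal(sort(gt2$phy$tip.label), sort(gt$phy$tip.label))
    expect_equal(phangorn::RF.dist(ape::unroot(gt$phy),
                                   ape::unroot(gt2$phy)), 0)
    expect_equal(sum(gt2$phy$edge.length), sum(gt$phy$edge.length))
  }
})

test_that("rooting on an outgroup gives the forced bipartition", {
  gt <- read_gene_tree("(a_x:1,b_y:1,(c_z:1,d_z:1):1);")
  r <- root_by_outgroup(gt, c("c_z", "d_z"))
  expect_true(ape::is.rooted(r$phy))
  root <- length(r$phy$tip.label) + 1L
  kid_sets <- lapply(r$phy$edge[r$phy$edge[, 1] == root, 2], function(k) {
    sort(r$phy$tip.label[phangorn::Descendants(r$phy, k, "tips")[[1]]])
  })
  expect_true(any(vapply(kid_sets, identical, logical(1),
                         y = c("c_z", "d_z"))))
  # an already correctly rooted tree comes back unchanged
  expect_identical(root_by_outgroup(r, c("c_z", "d_z")), r)
})

test_that("rooting splits ingroup/outgroup exactly as an edge scan does", {
  set.seed(11)
  for (i in 1:15) {
    n <- 12
    gt <- rand_gene_tree(n, species_pool = c("spA1", "spB1", "spD1"))
    # graft an outgroup cherry so the outgroup is a true split
    nwk <- sprintf("((ogA_spF1:1,ogB_spF1:1):1,%s);",
                   sub(";$", "", write_gene_tree(gt)))
    g2 <- read_gene_tree(nwk)
    un <- g2
    un$phy <- ape::unroot(un$phy)
    r <- root_by_outgroup(un, c("ogA_spF1", "ogB_spF1"))
    root <- length(r$phy$tip.label) + 1L
    kids <- r$phy$edge[r$phy$edge[, 1] == root, 2]
    sides <- lapply(kids, function(k) {
      sort(r$phy$tip.label[phangorn::Descendants(r$phy, k, "tips")[[1]]])
    })
    expect_true(any(vapply(sides, identical, logical(1),
                           y = c("ogA_spF1", "ogB_spF1"))))
    expect_setequal(unlist(sides), g2$phy$tip.label)
  }
})

test_that("non-monophyletic outgroups are rejected with the intruders named", {
  gt <- read_gene_tree("((a_x:1,c_z:1):1,(b_y:1,d_z:1):1);")
  expect_error(root_by_outgroup(gt, c("c_z", "d_z")), "monophyletic")
})

test_that("lca matches the path-intersection oracle", {
  set.seed(3)
  gt <- rand_gene_tree(20)
  phy <- gt$phy
  expect_equal(lca(gt, phy$tip.label[4]), 4L)            # single leaf
  expect_equal(lca(gt, phy$tip.label), 21L)              # all leaves -> root
  expect_error(lca(gt, character(0)), "empty")
  for (i in 1:30) {
    tips <- sample(seq_len(20), sample(2:5, 1))
    expect_equal(lca(gt, phy$tip.label[tips]), oracle_lca(phy, tips))
  }
})

test_that("locus tables get per-chromosome ranks and reject bad intervals", {
  loci <- as_gene_loci(data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    chrom = c("c1", "c1", "c2", "c1"),
    start = c(500, 100, 10, 900), end = c(600, 200, 20, 950),
    strand = "+"))
  expect_equal(loci$rank[match(c("g2", "g1", "g4"), loci$gene_id)], 1:3)
  expect_equal(loci$rank[loci$gene_id == "g3"], 1)
  expect_error(as_gene_loci(data.frame(
    gene_id = "g", chrom = "c", start = 5, end = 5, strand = "+")),
    "start must be < end")
})

test_that("BED and BLAST-tabular readers round-trip and filter", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t200\tgX\t0\t+", "c1\t300\t400\tgY\t0\t-"), bed)
  loci <- read_gene_loci(bed)
  expect_equal(loci$gene_id, c("gX", "gY"))
  expect_equal(loci$rank, c(1, 2))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("gX", "gY", 99, 100, 0, 0, 1, 100, 1, 100, "1e-50",
                       200), collapse = "\t"),
               paste(c("gY", "gX", 99, 100, 0, 0, 1, 100, 1, 100, "1e-40",
                       200), collapse = "\t"),
               paste(c("gX", "gZ", 99, 100, 0, 0, 1, 100, 1, 100, "1e-3",
                       200), collapse = "\t")), tsv)
  pairs <- read_homolog_pairs(tsv, e_value_max = 1e-10)
  expect_equal(nrow(pairs), 1L)  # dedup + E-value gate
  expect_equal(pairs$evalue, 1e-50)
})
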