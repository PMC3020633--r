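test_that("textbook reconciliation instances count correctly", {
  map <- c(a = "A", b = "B", c = "C", d = "D",
           a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  # concordant one-allele tree: no extra lineages
  expect_equal(count_deep_coalescences(rt("((a,b),c);"), sp3(), map), 0)
  # one discordant triplet: one extra lineage
  expect_equal(count_deep_coalescences(rt("((a,c),b);"), sp3(), map), 1)
  # two alleles per species, maximally interleaved: one extra lineage
  # leaves each tip branch
  expect_equal(count_deep_coalescences(rt("((a1,b1),(a2,b2));"),
                                       rt("(A,B);"), map), 2)
  # species sampled nowhere contribute empty clusters, which add nothing
  expect_equal(count_deep_coalescences(rt("((a,b),c);"), sp4_ladder(),
                                       map), 0)
  # two alleles of one species coalesce inside their own tip branch at no
  # cost when they are sisters
  expect_equal(count_deep_coalescences(rt("((a1,a2),b);"), rt("(A,B);"),
                                       map), 0)
  # but an allele pair broken up by another species costs one
  expect_equal(count_deep_coalescences(rt("((a1,b1),a2);"), rt("(A,B);"),
                                       map), 1)
})

test_that("the brute-force oracle agrees on the textbook instances", {
  map <- c(a = "A", b = "B", c = "C",
           a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_equal(brute_force_deep_coalescences(rt("((a,b),c);"), sp3(), map), 0)
  expect_equal(brute_force_deep_coalescences(rt("((a,c),b);"), sp3(), map), 1)
  expect_equal(brute_force_deep_coalescences(rt("((a1,b1),(a2,b2));"),
                                             rt("(A,B);"), map), 2)
  expect_error(brute_force_deep_coalescences(ape::rtree(9), sp3(),
                                             auto_map(ape::rtree(9))),
               "too large")
})

test_that("fast count equals the oracle on random instances", {
  set.seed(202)
  for (i in 1:40) {
    inst <- random_instance(sample(4:6, 1),
                            if (i %% 2) sp3() else sp4_balanced())
    expect_equal(
      count_deep_coalescences(inst$gene, inst$species, inst$map),
      brute_force_deep_coalescences(inst$gene, inst$species, inst$map),
      info = ape::write.tree(inst$gene))
  }
})

test_that("counts are invariant to child order", {
  set.seed(7)
  for (i in 1:10) {
    inst <- random_instance(6, sp4_ladder())
    rot <- ape::rotateConstr(inst$gene, rev(sort(inst$gene$tip.label)))
    expect_equal(count_deep_coalescences(rot, inst$species, inst$map),
                 count_deep_coalescences(inst$gene, inst$species, inst$map))
  }
})

test_that("adding alleles never decreases, pruning species never increases", {
  set.seed(11)
  for (i in 1:15) {
    inst <- random_instance(6, sp3())
    base <- count_deep_coalescences(inst$gene, inst$species, inst$map)

    # graft one extra allele of a random species as sister to a random tip
    host <- sample(inst$gene$tip.label, 1)
    sp_new <- sample(inst$species$tip.label, 1)
    new_lab <- paste0(tolower(sp_new), "x")
    g2 <- phytools::bind.tip(inst$gene, new_lab, edge.length = 0.1,
                             where = which(inst$gene$tip.label == host),
                             position = 0.5 * inst$gene$edge.length[
                               inst$gene$edge[, 2] ==
                                 which(inst$gene$tip.label == host)])
    map2 <- c(inst$map, setNames(sp_new, new_lab))
    expect_gte(count_deep_coalescences(g2, inst$species, map2), base)

    # prune every allele of one sampled species
    victim <- sample(unique(inst$map), 1)
    drop <- names(inst$map)[inst$map == victim &
                              names(inst$map) %in% inst$gene$tip.label]
    if (length(drop) < length(inst$gene$tip.label) - 1) {
      g3 <- ape::drop.tip(inst$gene, drop)
      expect_lte(count_deep_coalescences(g3, inst$species, inst$map), base)
    }
  }
})

test_that("polytomies are counted as given", {
  map <- c(a = "A", b = "B", c = "C", d = "D")
  poly <- rt("((a,b,c),d);")
  # the unresolved (a,b,c) clade leaves two lineages crossing the {A,B}
  # branch of the ladder species tree
  expect_equal(count_deep_coalescences(poly, sp4_ladder(), map), 1)
  expect_equal(brute_force_deep_coalescences(poly, sp4_ladder(), map), 1)
})

test_that("reconciliation inputs are validated", {
  map <- c(a = "A", b = "B", c = "C")
  expect_error(count_deep_coalescences(rt("((a,b),x);"), sp3(), map),
               "missing from taxon map")
  expect_error(count_deep_coalescences(rt("((a,b),c);"), rt("(A,B);"), map),
               "absent from species tree")
  unrooted <- ape::unroot(ape::rtree(4, tip.label = c("a", "b", "c", "c2")))
  expect_error(count_deep_coalescences(unrooted, sp3(),
                                       c(map, c2 = "C")), "rooted")
})

test_that("newick and taxon-map files round-trip", {
  d <- withr::local_tempdir()
  trees <- simulate_replicate(two_deme_model(), tibble::tibble(
    locus = c("L1", "L2"), A = c(3, 2), B = c(2, 3)), seed = 3)
  p <- file.path(d, "trees.nwk")
  write_gene_trees(trees, p)
  back <- read_gene_trees(p)
  expect_length(back, 2)
  expect_identical(ape::write.tree(back[[1]]), ape::write.tree(trees[[1]]))

  map <- c(`A|1` = "A", `A|2` = "A", `B|1` = "B")
  mp <- file.path(d, "map.tsv")
  write_taxon_map(map, mp)
  expect_identical(read_taxon_map(mp), map)

  # headerless two-column files are accepted too
  writeLines(c("x\tX", "y\tY"), mp)
  expect_identical(read_taxon_map(mp), c(x = "X", y = "Y"))
  writeLines(c("x\tX", "x\tY"), mp)
  expect_error(read_taxon_map(mp), "duplicate")
})

test_that("outgroup rooting places the root on the outgroup edge", {
  unrooted <- ape::unroot(rt("((a,b),(c,d));"))
  rooted <- root_with_outgroup(unrooted, "d")
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("a", "b", "c")))
  expect_error(root_with_outgroup(unrooted, "zz"), "absent")
})
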