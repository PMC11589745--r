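tm <- taxon_group_map()
tm3 <- taxon_group_map(groups = c("A", "B", "C"), recipient = "A")

test_that("gene-tree parsing decodes labels and supports", {
  gt <- parse_gene_tree("((A|query|q1,A|sp1|t1)95,(B|sp2|t2,B|sp3|t3)88);")
  expect_equal(ape::Ntip(gt$phy), 4L)
  expect_setequal(gt$supports[!is.na(gt$supports)], c(95, 88))
  expect_equal(sum(gt$leaves$is_query), 1L)
  expect_equal(gt$leaves$group,
               c("A", "A", "B", "B"))
  expect_error(parse_gene_tree("((a,b);"), "unparseable")
  expect_error(parse_gene_tree("(A|x|1,B|y|2);"), "at least 3")
})

test_that("fractional supports are rescaled with a warning", {
  expect_warning(
    gt <- parse_gene_tree("((A|query|q1,A|s|t1)0.95,(B|s|t2,B|s|t3)0.8);"),
    "rescaling")
  expect_setequal(gt$supports[!is.na(gt$supports)], c(95, 80))
  expect_error(parse_gene_tree("((A|query|q1,A|s|t1)950,(B|s|t2,B|s|t3)80);"),
               "outside")
})

test_that("parse-write-parse round-trips topology and supports", {
  cfg <- sim_config(seed = 15, n_genes = 50, support_spread = 15,
                    support_mean = 70)
  sims <- simulate_gene_trees(cfg)
  for (nk in sims$newicks[seq(1, 50, by = 5)]) {
    gt <- parse_gene_tree(nk)
    rt <- parse_gene_tree(ape::write.tree(gt$phy))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gt$phy),
                                           ape::unroot(rt$phy))), 0)
    expect_identical(sort(gt$supports), sort(rt$supports))
  }
})

test_that("monophyly follows bipartition semantics with supports", {
  gt <- parse_gene_tree("((A|query|q1,A|query|q2)95,(B|s|t1,B|s|t2));")
  m <- is_monophyletic_set(gt, c("A|query|q1", "A|query|q2"))
  expect_true(m$monophyletic)
  expect_equal(m$support, 95)

  gt2 <- parse_gene_tree("((A|query|q1,B|s|t1),(A|query|q2,B|s|t2));")
  expect_false(is_monophyletic_set(gt2, c("A|query|q1", "A|query|q2"))$monophyletic)
  # singleton convention
  expect_true(is_monophyletic_set(gt2, "A|query|q1")$monophyletic)
  expect_error(is_monophyletic_set(gt2, "nope"), "unknown leaf")
})

test_that("monophyly agrees with exhaustive bipartition enumeration", {
  # all unrooted topologies on 6 leaves, every non-trivial subset
  trees <- phangorn::allTrees(6, rooted = FALSE,
                              tip.label = sprintf("G|sp|t%d", 1:6))
  subsets <- unlist(lapply(2:5, function(k)
    utils::combn(6, k, simplify = FALSE)), recursive = FALSE)
  for (ti in seq(1, length(trees), by = 7)) {
    phy <- trees[[ti]]                # [[ ]] reattaches compressed labels
    gt <- parse_gene_tree(ape::write.tree(phy))
    for (s in subsets) {
      expect_equal(is_monophyletic_set(gt, phy$tip.label[s])$monophyletic,
                   oracle_monophyletic(phy, s))
    }
  }
})

test_that("sister finding matches the smallest-superset-clade oracle", {
  set.seed(1001)
  for (rep in 1:60) {
    n <- sample(6:12, 1)
    nq <- sample(1:3, 1)
    nk <- random_gene_tree_newick(n, n_query = nq)
    gt <- parse_gene_tree(nk)
    phy <- gt$phy
    qidx <- which(gt$leaves$is_query)
    sis <- find_sister(gt, tm3)
    orc <- oracle_sister(phy, qidx)
    if (is.null(orc)) {
      expect_equal(sis$status, "unresolved")
    } else {
      expect_equal(sis$status, "ok")
      expect_setequal(sis$sister, phy$tip.label[orc])
    }
  }
})

test_that("scattered queries whose smallest clade is the whole tree are unresolved", {
  gt <- parse_gene_tree("((A|query|q1,B|s|t1)90,(A|query|q2,B|s|t2)80);")
  expect_equal(find_sister(gt, tm3)$status, "unresolved")
  expect_equal(call_hgt(gt, tm3)$status, "unresolved")
})

test_that("HGT calls apply the support threshold and donor rules", {
  mk <- function(sup)
    parse_gene_tree(sprintf(
      "((Excavata|query|q1,(Fungi|f|t1,Fungi|f|t2)90)%d,((Metazoa|m|t3,Metazoa|m|t4)88,(Bacteria|b|t5,Bacteria|b|t6)95)80);",
      sup))
  hi <- call_hgt(mk(80), tm)
  expect_equal(hi$status, "supported")
  expect_equal(hi$donor_group, "Fungi")
  expect_equal(hi$key_support, 80)
  lo <- call_hgt(mk(50), tm)
  expect_equal(lo$status, "unsupported")
  expect_equal(lo$donor_group, "Fungi")
  # raising the threshold never converts unsupported -> supported
  for (s in c(0, 30, 59, 60, 61, 90, 100)) {
    a <- call_hgt(mk(70), tm, support_min = s)$status
    b <- call_hgt(mk(70), tm, support_min = min(100, s + 10))$status
    expect_false(a == "unsupported" && b == "supported")
  }
})

test_that("mixed sisters need a strict majority for a donor", {
  # sister 2 Fungi + 1 Metazoa: majority Fungi
  gt <- parse_gene_tree(
    "((Excavata|query|q1,((Fungi|f|t1,Fungi|f|t2)90,Metazoa|m|t3)85)95,(Bacteria|b|t4,Bacteria|b|t5)99);")
  call <- call_hgt(gt, tm)
  expect_equal(call$donor_group, "Fungi")
  expect_false(call$donor_uniform)
  # sister 1 Fungi + 1 Metazoa: no majority, unresolved
  gt2 <- parse_gene_tree(
    "((Excavata|query|q1,(Fungi|f|t1,Metazoa|m|t3)90)95,(Bacteria|b|t4,Bacteria|b|t5)99);")
  call2 <- call_hgt(gt2, tm)
  expect_equal(call2$status, "unresolved")
  expect_true(is.na(call2$donor_group))
  # support-absent key branch cannot certify a transfer
  gt3 <- parse_gene_tree(
    "((Excavata|query|q1,(Fungi|f|t1,Fungi|f|t2)90),(Bacteria|b|t4,Bacteria|b|t5)99);")
  expect_equal(call_hgt(gt3, tm)$status, "unsupported")
})

test_that("family topology distinguishes singleton, mono and mixed", {
  cfg <- sim_config(seed = 41)
  mono <- simulate_gene_tree(cfg, "hgt", donor = "Bacteria", n_query = 2)
  gt <- parse_gene_tree(mono$newick)
  expect_equal(classify_family(gt), "mono")
  expect_equal(call_hgt(gt, tm)$family_topology, "mono")
  expect_equal(call_hgt(gt, tm)$donor_group, "Bacteria")

  single <- simulate_gene_tree(cfg, "vertical")
  expect_equal(classify_family(parse_gene_tree(single$newick)), "singleton")

  mixed <- parse_gene_tree(
    "(((Excavata|query|q1,Fungi|f|t1)90,(Excavata|query|q2,Metazoa|m|t2)85)80,(Bacteria|b|t3,Bacteria|b|t4)99);")
  expect_equal(classify_family(mixed), "mixed")
  # internal consistency with the monophyly primitive
  ql <- mixed$leaves$label[mixed$leaves$is_query]
  expect_false(is_monophyletic_set(mixed, ql)$monophyletic)
})

test_that("rooting strategy falls back deterministically and is recorded", {
  cfg <- sim_config(seed = 51)
  nk <- simulate_gene_tree(cfg, "hgt", donor = "Fungi")$newick
  gt <- parse_gene_tree(nk)
  gt$phy <- ape::unroot(gt$phy)
  rooted <- root_gene_tree(gt, tm)
  expect_match(attr(rooted, "rooting"), "outgroup")
  expect_true(ape::is.rooted(rooted$phy))

  # no prokaryotes, no branch lengths: farthest-leaf fallback
  gt2 <- parse_gene_tree(
    "(((A|query|q1,(B|s|t1,B|s|t2)90)80,C|s|t3)70,(C|s|t4,B|s|t5)60);")
  gt2$phy <- ape::unroot(gt2$phy)
  rooted2 <- root_gene_tree(gt2, tm3)
  expect_equal(attr(rooted2, "rooting"), "farthest-leaf")
  sis <- find_sister(rooted2, tm3)
  expect_setequal(sis$sister, c("B|s|t1", "B|s|t2"))

  # rooting never changes a bipartition-mode monophyly verdict
  set.seed(7)
  for (i in 1:30) {
    nk <- random_gene_tree_newick(8, n_query = 2)
    g <- parse_gene_tree(nk)
    qs <- g$leaves$label[g$leaves$is_query]
    v1 <- is_monophyletic_set(g, qs)$monophyletic
    g2 <- root_gene_tree(g, tm3, strategy = "farthest-leaf")
    expect_equal(is_monophyletic_set(g2, qs)$monophyletic, v1)
  }
})

test_that("verdicts are invariant under leaf-id renaming", {
  cfg <- sim_config(seed = 61, support_mean = 85, support_spread = 0)
  nk <- simulate_gene_tree(cfg, "hgt", donor = "Alveolata", n_query = 2)$newick
  gt <- parse_gene_tree(nk)
  before <- call_hgt(gt, tm)
  # rename ids (third field) only; groups and species stay
  gt2 <- gt
  gt2$phy$tip.label <- sub("\\|([^|]+)$", "|renamed_\\1", gt$phy$tip.label)
  gt2$leaves$label <- gt2$phy$tip.label
  after <- call_hgt(gt2, tm)
  expect_equal(after$status, before$status)
  expect_equal(after$donor_group, before$donor_group)
  expect_equal(after$key_support, before$key_support)
  expect_equal(after$family_topology, before$family_topology)
})

test_that("donor summaries tabulate supported calls by family topology", {
  cfg <- sim_config(seed = 71, n_genes = 60)
  sims <- simulate_gene_trees(cfg, n_query = rep(c(1L, 2L), 30))
  calls <- call_hgt_batch(sims$newicks, tm, ids = sims$truth$tree_id)
  expect_equal(nrow(calls), 60L)
  ds <- summarize_donors(calls)
  expect_equal(sum(ds$n), sum(calls$status == "supported"))
  expect_true(all(ds$donor_group != tm$recipient))
})
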