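# Tree structure, node classification, shortcut dispatch, traversal, NNI,
# random topologies.

test_that("down-node classification follows the terminal-children encoding", {
  phy <- read_newick("(((a,b),(c,d)),((e,(f,g)),h));")
  cls <- classify_node(phy)
  tr <- phyfuse:::as_cptree(phy)
  down <- setdiff(tr$postorder, tr$root)
  dcls <- cls[match(down, tr$postorder)]
  # both children terminal -> down_3; both internal -> down_0;
  # left-terminal -> down_1; right-terminal -> down_2
  expect_setequal(unique(names(dcls)),
                  c("down_3", "down_0", "down_1", "down_2"))
  expect_equal(sum(names(dcls) == "down_3"), 3L)  # (a,b), (c,d), (f,g)
  expect_equal(length(dcls), length(phy$tip.label) - 2L)
  expect_error(classify_node(phy, node = 1L), "leaf")
})

test_that("classification partitions the N-2 down nodes on random trees", {
  set.seed(23)
  for (n in c(5, 9, 16, 33)) {
    phy <- random_tree(n)
    tr <- phyfuse:::as_cptree(phy)
    cls <- classify_node(phy)
    down_cls <- cls[match(setdiff(tr$postorder, tr$root), tr$postorder)]
    counts <- table(factor(down_cls, levels = 0:3))
    expect_equal(sum(counts), n - 2L)
  }
})

test_that("the scaler shortcut reproduces all four flag rows", {
  expect_identical(shortcut(0, 0), 0L)
  expect_identical(shortcut(0, 1), 1L)
  expect_identical(shortcut(1, 0), 2L)
  expect_identical(shortcut(1, 1), 3L)
  expect_identical(shortcut(c(0, 1), c(1, 1)), c(1L, 3L))
  expect_error(shortcut(2, 0), "0 or 1")
})

test_that("the variant table enumerates 16 distinct shape-times-shortcut ids", {
  vt <- variant_table()
  expect_equal(nrow(vt), 16L)
  expect_equal(anyDuplicated(vt$id), 0L)
  expect_setequal(vt$x, 0:3)
  expect_setequal(vt$T, 0:3)
  expect_equal(vt$T, 2L * vt$S + vt$N)
  expect_equal(vt$id[vt$x == 3 & vt$T == 1], "down_3_1")
})

test_that("postorder visits children before parents, root last", {
  expect_length(postorder_nodes(read_newick("(a,b,c);")), 2L)  # resolved root
  set.seed(31)
  phy <- random_tree(60)
  tr <- phyfuse:::as_cptree(phy)
  po <- postorder_nodes(phy)
  expect_equal(po[length(po)], tr$root)
  pos <- match(seq_len(2L * 60L - 1L), po)
  for (v in po)
    for (ch in tr$child[, v])
      if (ch > 60L) expect_true(pos[ch] < pos[v])
})

test_that("newick round-trips preserve labels, lengths and splits", {
  txt <- "(a:0.1,b:0.2,(c:0.1,d:0.1):0.05);"
  phy <- read_newick(txt)
  expect_equal(sort(phy$tip.label), c("a", "b", "c", "d"))
  rt <- read_newick(write_newick(phy))
  expect_equal(sort(rt$tip.label), sort(phy$tip.label))
  expect_equal(sort(rt$edge.length), sort(phy$edge.length))
  # zero-length branch preserved
  z <- read_newick(write_newick(read_newick("((a:0,b:0.1):0.2,c:0.1);")))
  expect_true(any(z$edge.length == 0))
  set.seed(37)
  phy60 <- random_tree(60)
  expect_setequal(tree_splits(read_newick(write_newick(phy60))),
                  tree_splits(phy60))
  expect_error(read_newick("((a,b);"), "parenthes")
})

test_that("NNI around a quartet edge yields the two alternative topologies", {
  phy <- read_newick("((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  tr <- phyfuse:::as_cptree(phy)
  edges <- phyfuse:::internal_edges(tr)
  expect_length(edges, 1L)
  nb <- nni_neighbors(phy, edges[1])
  keys <- sort(vapply(nb, function(t) tree_splits(t), ""))
  expect_setequal(keys, c("b|d", "b|c"))  # {a,c|b,d} and {a,d|b,c}
  expect_error(nni_neighbors(read_newick("(a,b,c);")), "4 taxa")
})

test_that("NNI is an involution and produces valid distinct binary trees", {
  set.seed(41)
  phy <- random_tree(10)
  tr <- phyfuse:::as_cptree(phy)
  base <- sort(tree_splits(phy))
  all_keys <- character(0)
  for (e in phyfuse:::internal_edges(tr)) {
    for (k in 1:2) {
      t1 <- phyfuse:::cptree_nni(tr, e, k)
      expect_false(setequal(tree_splits(t1), base))
      t2 <- phyfuse:::cptree_nni(t1, e, k)
      expect_setequal(tree_splits(t2), base)
      p1 <- phyfuse:::as_phylo(t1)
      expect_true(ape::is.binary(p1) && ape::is.rooted(p1))
      all_keys <- c(all_keys, paste(sort(tree_splits(t1)), collapse = ";"))
    }
  }
  expect_equal(anyDuplicated(all_keys), 0L)  # all neighbors distinct
})

test_that("random trees are deterministic under a seed and uniform over topologies", {
  set.seed(43)
  t1 <- random_tree(8)
  set.seed(43)
  t2 <- random_tree(8)
  expect_equal(write_newick(t1), write_newick(t2))
  # n = 3 has a single unrooted topology
  expect_length(tree_splits(random_tree(3)), 0L)
  # chi-squared uniformity over the 105 unrooted 6-taxon topologies
  set.seed(47)
  n_draws <- 10500L
  keys <- vapply(seq_len(n_draws), function(i)
    paste(sort(tree_splits(random_tree(6,
      branch_fn = function(n) rep(0.1, n)))), collapse = ";"), "")
  tab <- table(keys)
  expect_equal(length(tab), 105L)
  chisq <- sum((tab - n_draws / 105)^2 / (n_draws / 105))
  expect_lt(chisq, qchisq(0.999, df = 104))
})

test_that("caterpillar trees have the ladder shape used by the accounting scenario", {
  phy <- caterpillar_tree(6)
  tr <- phyfuse:::as_cptree(phy)
  cls <- classify_node(phy)
  down <- setdiff(tr$postorder, tr$root)
  dcls <- names(cls[match(down, tr$postorder)])
  expect_equal(sum(dcls == "down_3"), 1L)        # single basal cherry
  expect_true(all(dcls[dcls != "down_3"] %in% c("down_1", "down_2")))
})
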