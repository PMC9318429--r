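test_that("composition_matrix validates, normalizes and rejects bad input", {
  X <- composition_matrix(rbind(c(2, 3, 5), c(1, 1, 2)), normalize = TRUE)
  expect_equal(unclass(X)[1, ], c(T1 = .2, T2 = .3, T3 = .5))
  expect_equal(unname(rowSums(X)), c(1, 1))
  expect_error(composition_matrix(rbind(c(-0.1, 1.1))), "negative")
  expect_error(composition_matrix(rbind(c(.2, .3))), "row sums")
  expect_error(composition_matrix(rbind(c(0, 0), c(1, 1)), normalize = TRUE), "zero total")
  expect_error(composition_matrix(matrix(.5, 2, 2), sample_ids = c("a", "a")),
               "duplicated sample")
})

test_that("amalgamate sums assigned columns and conserves mass", {
  x <- c(.1, .2, .3, .25, .15)
  X <- composition_matrix(matrix(x, 1))
  R <- amalgamation_matrix(c(1, 1, 2, 3, 3))
  expect_equal(unname(unclass(amalgamate(X, R))[1, ]), c(.3, .3, .4))
  # identity partition and single group
  expect_equal(unname(unclass(amalgamate(X, amalgamation_matrix(1:5)))[1, ]), x)
  expect_equal(unname(unclass(amalgamate(X, amalgamation_matrix(rep(1, 5))))[1, ]), 1)
  expect_error(amalgamate(X, amalgamation_matrix(c(1, 2, 2))), "does not match")
})

test_that("amalgamation conserves row sums and composes", {
  for (seed in 1:5) {
    X <- rcomp(6, 10, seed = seed, sparsity = 0.3)
    set.seed(seed + 100)
    a1 <- sample.int(6, 10, replace = TRUE)
    a1 <- match(a1, sort(unique(a1)))
    R1 <- amalgamation_matrix(a1)
    Y1 <- amalgamate(X, R1)
    expect_true(all(abs(rowSums(Y1) - rowSums(X)) < 1e-12))
    a2 <- sample.int(3, R1$k, replace = TRUE)
    a2 <- match(a2, sort(unique(a2)))
    R2 <- amalgamation_matrix(a2, taxon_ids = R1$group_ids)
    R21 <- amalgamation_matrix(a2[a1], k = R2$k)
    expect_equal(unname(unclass(amalgamate(Y1, R2))),
                 unname(unclass(amalgamate(X, R21))))
  }
})

test_that("amalgamation_matrix columns sum to one and empty groups are legal", {
  R <- amalgamation_matrix(c(1, 1, 3), k = 3)
  M <- as.matrix(R)
  expect_true(all(colSums(M) == 1))
  expect_true(all(M %in% c(0, 1)))
  expect_equal(unname(rowSums(M)), c(2, 0, 1))
  expect_error(amalgamation_matrix(c(1, 4), k = 3), "1..k")
})

test_that("node depth matches the ancestor count, root is 0", {
  tr <- example_taxonomy()
  expect_equal(node_depth(tr, tr$root), 0L)
  expect_equal(node_depth(tr, taxon_node(tr, "Taxon 1")), 1L)
  expect_equal(node_depth(tr, taxon_node(tr, "Taxon 2")), 5L)
  chain <- tree_from_lineages("a;b")
  expect_equal(node_depth(chain, taxon_node(chain, "b")), 2L)
  expect_error(node_depth(tr, 9999), "unknown node")
})

test_that("lowest multi-child ancestor skips unary chains", {
  tr <- example_taxonomy()
  t12 <- taxon_node(tr, "Taxon 12"); t13 <- taxon_node(tr, "Taxon 13")
  expect_equal(lowest_multichild_ancestor(tr, t12), tr$parent[t12])
  expect_equal(lowest_multichild_ancestor(tr, t13), tr$parent[tr$parent[t13]])
  expect_equal(lowest_multichild_ancestor(tr, t12),
               lowest_multichild_ancestor(tr, t13))
  # leaf under a long unary chain below a binary node
  tr2 <- tree_from_lineages(c("A;u1;u2;u3;x", "A;y"))
  expect_equal(tr2$label[lowest_multichild_ancestor(tr2, taxon_node(tr2, "x"))], "A")
  one <- tree_from_lineages("solo")
  expect_error(lowest_multichild_ancestor(one, taxon_node(one, "solo")),
               "no multi-child ancestor")
})

test_that("depth and A* agree with path-walking oracles on random trees", {
  for (seed in 1:8) {
    tr <- rtree_lineages(12, seed = seed)
    for (leaf in tree_leaves(tr)) {
      expect_identical(node_depth(tr, leaf), oracle_depth(tr, leaf))
      expect_identical(lowest_multichild_ancestor(tr, leaf),
                       oracle_astar(tr, leaf))
    }
  }
})

test_that("reduce_tree merges siblings and collapses the emptied parent", {
  # binary parent P: the merged leaf replaces both children under parent(P)
  tr <- tree_from_lineages(c("A;P;a", "A;P;b", "A;c"))
  a <- taxon_node(tr, "a"); b <- taxon_node(tr, "b")
  red <- reduce_tree(tr, a, b)
  new <- attr(red, "new_leaf")
  expect_equal(length(tree_leaves(red)), 2L)
  expect_equal(red$label[red$parent[new]], "A")
  expect_equal(node_depth(red, new), 2L)
  # 2-of-3 siblings: parent keeps two children
  tr3 <- tree_from_lineages(c("A;P;a", "A;P;b", "A;P;c", "A;d"))
  red3 <- reduce_tree(tr3, taxon_node(tr3, "a"), taxon_node(tr3, "b"))
  new3 <- attr(red3, "new_leaf")
  P <- red3$parent[new3]
  expect_equal(red3$nchild[P], 2L)
  expect_equal(node_depth(red3, new3), node_depth(red3, P) + 1L)
})

test_that("reduce_tree drops one leaf per call and preserves untouched path lengths", {
  set.seed(42)
  for (seed in 1:5) {
    tr <- rtree_lineages(10, seed = seed)
    leaves <- tree_leaves(tr)
    before <- vapply(leaves, function(id) root_path_length(tr, id), 0)
    pick <- sample(length(leaves), 2L)
    red <- reduce_tree(tr, leaves[pick[1]], leaves[pick[2]])
    kept <- setdiff(names(leaves), names(leaves)[pick])
    expect_equal(length(tree_leaves(red)), length(leaves) - 1L)
    after <- vapply(kept, function(tx) root_path_length(red, taxon_node(red, tx)), 0)
    expect_equal(after, before[kept])
  }
})

test_that("merged leaf depth equals attachment depth + 1 on unit trees", {
  # verified against a rebuild of the expected taxonomy from lineage strings
  tr <- tree_from_lineages(c("A;B;x", "A;B;y", "A;B;z", "A;w"))
  x <- taxon_node(tr, "x"); y <- taxon_node(tr, "y")
  att <- lowest_multichild_ancestor(tr, x)
  red <- reduce_tree(tr, x, y, label = "xy", taxon = "xy")
  expect_equal(node_depth(red, attr(red, "new_leaf")), node_depth(red, att) + 1L)
  rebuilt <- tree_from_lineages(c("A;B;xy", "A;B;z", "A;w"))
  expect_equal(node_depth(red, taxon_node(red, "xy")),
               node_depth(rebuilt, taxon_node(rebuilt, "xy")))
  expect_error(reduce_tree(tr, x, x), "itself")
  expect_error(reduce_tree(tr, tr$root, y), "must be leaves")
})

test_that("compose_path replays merges into a valid partition", {
  X <- rcomp(4, 5, seed = 3)
  path <- run_hpaa(X, loss = "sdi")
  # k = p is the identity, k = 1 one group
  expect_equal(compose_path(path, 5)$assignment, 1:5)
  expect_equal(compose_path(path, 1)$assignment, rep(1L, 5))
  for (k in 1:5) {
    R <- compose_path(path, k)
    expect_equal(R$k, k)
    expect_true(all(colSums(as.matrix(R)) == 1))
  }
  expect_error(compose_path(path, 0), "must lie in")
  expect_error(compose_path(path, 6), "must lie in")
})

test_that("compose_path matches a hand-executed merge list", {
  # p = 5: merge (T1,T2), then (T1+T2,T3), then (T4,T5); cutting at k = 3
  # keeps only the first two merges, giving {1,2,3}, {4}, {5}
  fake <- structure(list(
    merge = rbind(c(-1L, -2L), c(-3L, 1L), c(-5L, -4L), c(2L, 3L)),
    p = 5L, taxon_ids = paste0("T", 1:5),
    steps = data.frame(label = c("T1+T2", "T1+T2+T3", "T4+T5", "all"),
                       stringsAsFactors = FALSE)), class = "merge_path")
  R <- compose_path(fake, 3)
  expect_equal(R$assignment, c(1L, 1L, 1L, 2L, 3L))
  expect_equal(R$group_ids, c("T1+T2+T3", "T4", "T5"))
  expect_equal(compose_path(fake, 2)$assignment, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(compose_path(fake, 5)$assignment, 1:5)
})
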