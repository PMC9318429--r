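test_that("active_pairs enumerates candidates per hierarchy mode", {
  expect_equal(ncol(active_pairs(NULL, NULL, 3, "none")), 3L)
  expect_equal(ncol(active_pairs(NULL, NULL, 5, "none")), 10L)
  expect_error(active_pairs(NULL, NULL, 3, "weak"), "requires a taxonomy")

  tr <- example_taxonomy()
  leaves <- tree_leaves(tr)
  taxa <- names(leaves)
  lab <- function(pairs) apply(pairs, 2, function(pr) paste(sort(taxa[pr]), collapse = " / "))
  weak <- lab(active_pairs(tr, unname(leaves), length(leaves), "weak"))
  strong <- lab(active_pairs(tr, unname(leaves), length(leaves), "strong"))
  expect_true("Taxon 2 / Taxon 3" %in% weak)
  expect_true("Taxon 12 / Taxon 13" %in% weak)
  expect_false("Taxon 26 / Taxon 27" %in% weak)
  expect_true("Taxon 2 / Taxon 3" %in% strong)
  expect_false("Taxon 12 / Taxon 13" %in% strong)
})

test_that("greedy sdi step picks the minimum inner-product pair", {
  # single sample (.6,.3,.1): inner products .18 (1,2), .06 (1,3), .03 (2,3)
  X <- composition_matrix(matrix(c(.6, .3, .1), 1))
  path <- run_hpaa(X, loss = "sdi")
  expect_equal(c(path$steps$left[1], path$steps$right[1]), c("T2", "T3"))
  expect_equal(path$steps$step_loss[1], 2 * 0.03)
})

test_that("identical columns merge first at zero cost under bc", {
  M <- cbind(c(.4, .1, .2), c(.2, .3, .1), c(.2, .3, .1), c(.2, .3, .6))
  X <- composition_matrix(M)
  path <- run_hpaa(X, loss = "bc")
  expect_equal(sort(c(path$steps$left[1], path$steps$right[1])), c("T2", "T3"))
  expect_equal(path$steps$step_loss[1], 0)
})

test_that("cost ties break to the lexicographically smallest pair", {
  # perfectly symmetric data: all pairs tie, (1,2) must win, reproducibly
  X <- composition_matrix(matrix(rep(.25, 8), 2))
  p1 <- run_hpaa(X, loss = "sdi")
  p2 <- run_hpaa(X, loss = "sdi")
  expect_equal(c(p1$steps$left[1], p1$steps$right[1]), c("T1", "T2"))
  expect_identical(p1$steps, p2$steps)
})

test_that("a p = 2 path is a single step ending in the ones column", {
  X <- rcomp(4, 2, seed = 2)
  path <- run_hpaa(X, loss = "swi")
  expect_equal(nrow(path$steps), 1L)
  ct <- cut(path, 1)
  expect_equal(unname(unclass(ct$scores)[, 1]), rep(1, 4))
  expect_error(run_hpaa(rcomp(3, 1, seed = 1)), "at least two taxa")
})

test_that("paths are deterministic replays of the same inputs", {
  X <- rcomp(6, 10, seed = 5, sparsity = 0.3)
  tr <- rtree_lineages(10, seed = 5)
  colnames(X) <- names(tree_leaves(tr))
  X <- composition_matrix(unclass(X))
  for (loss in c("sdi", "bc")) {
    a <- run_hpaa(X, tr, loss = loss, hierarchy = "weak")
    b <- run_hpaa(X, tr, loss = loss, hierarchy = "weak")
    expect_identical(a$merge, b$merge)
    expect_identical(a$steps, b$steps)
  }
})

test_that("small-instance greedy choices match exhaustive search (sdi, none)", {
  for (seed in 1:6) {
    p <- sample(3:6, 1)
    X <- rcomp(4, p, seed = seed + 200, sparsity = 0.2)
    path <- run_hpaa(X, loss = "sdi")
    replay_path(path, function(t, cols, tree, leaf_of, j, jp) {
      pairs <- utils::combn(ncol(cols), 2L)
      costs <- apply(pairs, 2, function(pr)
        oracle_pair_cost("sdi", cols, pr[1], pr[2]))
      chosen <- oracle_pair_cost("sdi", cols, j, jp)
      expect_lte(chosen, min(costs) + 1e-12)
      NULL
    })
  }
})

test_that("guided paths only merge pairs sharing their lowest multi-child ancestor", {
  for (seed in 1:4) {
    tr <- rtree_lineages(10, seed = seed + 30)
    X <- rcomp(5, 10, seed = seed + 30, sparsity = 0.3)
    colnames(X) <- names(tree_leaves(tr))
    X <- composition_matrix(unclass(X))
    path <- run_hpaa(X, tr, loss = "sdi", hierarchy = "weak")
    replay_path(path, function(t, cols, tree, leaf_of, j, jp) {
      expect_equal(oracle_astar(tree, leaf_of[j]), oracle_astar(tree, leaf_of[jp]))
      NULL
    })
  }
})

test_that("strong mode never merges while a deeper eligible pair exists", {
  for (seed in 1:4) {
    tr <- rtree_lineages(10, seed = seed + 60)
    X <- rcomp(5, 10, seed = seed + 60)
    colnames(X) <- names(tree_leaves(tr))
    X <- composition_matrix(unclass(X))
    path <- run_hpaa(X, tr, loss = "sdi", hierarchy = "strong")
    replay_path(path, function(t, cols, tree, leaf_of, j, jp) {
      res <- oracle_active_set(tree, leaf_of, "strong")
      tree <- res$tree
      depth <- vapply(leaf_of, function(id) oracle_depth(tree, id), 0L)
      if (ncol(res$pairs) > 0L) {
        dmax <- max(depth[res$pairs[1, ]], depth[res$pairs[2, ]])
        expect_gte(min(depth[j], depth[jp]), dmax - 0L)  # both at eligible depth
        expect_true(any(apply(res$pairs, 2, function(pr)
          all(pr == c(j, jp)))))
      }
      list(tree = tree)
    })
  }
})

test_that("hierarchy and loss requirements are enforced", {
  X <- rcomp(3, 4, seed = 1)
  expect_error(run_hpaa(X, hierarchy = "weak"), "requires a taxonomy")
  expect_error(run_hpaa(X, loss = "wuf"), "requires a taxonomy")
  tr <- tree_from_lineages(c("A;x", "A;y"))
  expect_error(run_hpaa(X, tr, loss = "sdi"), "do not match")
})

test_that("cut returns consistent loadings, scores and loss report", {
  X <- rcomp(6, 8, seed = 9, sparsity = 0.2)
  path <- run_hpaa(X, loss = "sdi")
  full <- cut(path, 8)
  expect_equal(unname(unclass(full$scores)), unname(unclass(X)))
  expect_equal(full$loss_report$cum_pct_loss, 0)
  one <- cut(path, 1)
  expect_equal(one$loss_report$cum_pct_loss, 100)
  # alpha cumulative loss at k equals the sum of the first p - k step losses
  for (k in c(2, 4, 6)) {
    ct <- cut(path, k)
    expect_equal(ct$loss_report$cum_loss,
                 sum(path$steps$step_loss[seq_len(8 - k)]), tolerance = 1e-12)
    expect_equal(ct$loss_report$cum_loss,
                 total_alpha("sdi", X) - total_alpha("sdi", ct$scores),
                 tolerance = 1e-10)
  }
})

test_that("planted disjoint-support groups are recovered at k = g", {
  spec <- synth_spec(n_samples = 20L, n_taxa = 18L, groups = 3L, seed = 4L)
  sim <- simulate_compositions(spec, disjoint_support = TRUE)
  path <- run_hpaa(sim$X, loss = "sdi")
  R <- compose_path(path, 3)
  expect_equal(adjusted_rand(R$assignment, sim$true_partition), 1)
  # the first p - g merges are all within-group
  grp_of <- sim$true_partition
  names(grp_of) <- colnames(sim$X)
  replay_path(path, function(t, cols, tree, leaf_of, j, jp) {
    if (t <= 18 - 3) {
      taxa_j <- strsplit(colnames(cols)[j], "+", fixed = TRUE)[[1]]
      taxa_jp <- strsplit(colnames(cols)[jp], "+", fixed = TRUE)[[1]]
      expect_equal(length(unique(grp_of[c(taxa_j, taxa_jp)])), 1L)
    }
    NULL
  })
})

test_that("swi pseudocount option reproduces zero-replacement behaviour", {
  X <- rcomp(4, 6, seed = 13, sparsity = 0.5)
  eps <- 1e-6
  Xr <- unclass(X); Xr[Xr == 0] <- eps; Xr <- Xr / rowSums(Xr)
  a <- run_hpaa(X, loss = "swi", pseudocount = eps)
  b <- run_hpaa(composition_matrix(Xr, rownames(X), colnames(X)), loss = "swi")
  expect_equal(a$steps$step_loss, b$steps$step_loss, tolerance = 1e-12)
  expect_identical(a$steps$label, b$steps$label)
})

test_that("merge paths serialize to Newick with cumulative-loss heights", {
  X <- rcomp(4, 6, seed = 21)
  path <- run_hpaa(X, loss = "sdi")
  nwk <- path_to_newick(path)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, colnames(X))
  # root-to-tip distance equals the final cumulative percentage loss
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(unname(depths), rep(100, 6), tolerance = 1e-8)
})
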