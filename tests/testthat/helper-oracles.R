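# Shared fixtures and independent brute-force oracles. The oracles recompute
# every quantity from scratch (loops over samples/branches, full-matrix
# re-evaluation) and never touch the incremental state the package maintains.

rdir <- function(p) { g <- stats::rgamma(p, 1); g / sum(g) }

rcomp <- function(n, p, seed = 1, conc = 1, sparsity = 0) {
  set.seed(seed)
  M <- matrix(stats::rgamma(n * p, conc), n, p)
  if (sparsity > 0) {
    M[stats::runif(n * p) < sparsity] <- 0
    M[rowSums(M) == 0, 1] <- 1
  }
  M <- M / rowSums(M)
  colnames(M) <- paste0("T", seq_len(p))
  rownames(M) <- paste0("S", seq_len(n))
  composition_matrix(M)
}

rtree_lineages <- function(p, seed = 1) {
  simulate_taxonomy(synth_spec(n_samples = 2L, n_taxa = p, groups = 2L,
                               seed = seed,
                               tree_depth = max(4L, ceiling(log2(p)) + 1L),
                               zero_inflation = 0))
}

## --- from-scratch diversity totals -----------------------------------------

oracle_total_sdi <- function(X) {
  X <- unclass(X)
  sum(apply(X, 1, function(x) 1 - sum(x^2)))
}

oracle_total_swi <- function(X) {
  X <- unclass(X)
  sum(apply(X, 1, function(x) { x <- x[x > 0]; -sum(x * log(x)) }))
}

oracle_bc_dist <- function(X) as.matrix(vegan::vegdist(unclass(X), method = "bray"))

oracle_wuf_dist <- function(X, l, L) {
  X <- unclass(X)
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(l * abs(X[i, ] - X[j, ]))
    den <- sum(L * (X[i, ] + X[j, ]))
    D[i, j] <- if (den == 0) 0 else num / den
  }
  D
}

## --- path-walking tree oracles (no package helpers) ------------------------

oracle_depth <- function(tree, node) {
  d <- 0L
  while (!is.na(tree$parent[node])) { node <- tree$parent[node]; d <- d + 1L }
  d
}

oracle_astar <- function(tree, leaf) {
  node <- tree$parent[leaf]
  while (!is.na(node)) {
    kids <- sum(tree$active & !is.na(tree$parent) & tree$parent == node)
    if (kids > 1L) return(node)
    node <- tree$parent[node]
  }
  NA_integer_
}

oracle_root_path <- function(tree, node) {
  len <- 0
  while (!is.na(tree$parent[node])) { len <- len + tree$edge_length[node]; node <- tree$parent[node] }
  len
}

oracle_active_pairs <- function(tree, leaf_of, mode) {
  m <- length(leaf_of)
  all <- utils::combn(m, 2L)
  if (mode == "none") return(all)
  astar <- vapply(leaf_of, function(id) oracle_astar(tree, id), 0L)
  keep <- astar[all[1, ]] == astar[all[2, ]]
  if (mode == "strong") {
    depth <- vapply(leaf_of, function(id) oracle_depth(tree, id), 0L)
    dstar <- max(depth)
    keep <- keep & depth[all[1, ]] == dstar & depth[all[2, ]] == dstar
  }
  all[, keep, drop = FALSE]
}

## Active set including the strong-mode fallbacks (mirrors the documented
## rules; tree mutation delegates to the package's reduction operators).
oracle_active_set <- function(tree, leaf_of, mode) {
  pairs <- oracle_active_pairs(tree, leaf_of, mode)
  if (mode == "strong" && ncol(pairs) == 0L) {
    repeat {
      depth <- vapply(leaf_of, function(id) oracle_depth(tree, id), 0L)
      tree <- paar:::collapse_unary_parents(tree, leaf_of[depth == max(depth)])
      changed <- isTRUE(attr(tree, "changed"))
      pairs <- oracle_active_pairs(tree, leaf_of, "strong")
      if (ncol(pairs) > 0L || !changed) break
    }
    if (ncol(pairs) == 0L) {
      astar <- vapply(leaf_of, function(id) oracle_astar(tree, id), 0L)
      depth <- vapply(leaf_of, function(id) oracle_depth(tree, id), 0L)
      all <- utils::combn(length(leaf_of), 2L)
      deep_grp <- astar %in% astar[depth == max(depth)]
      keep <- astar[all[1, ]] == astar[all[2, ]] & deep_grp[all[1, ]] & deep_grp[all[2, ]]
      pairs <- all[, keep, drop = FALSE]
    }
  }
  list(pairs = pairs, tree = tree)
}

## --- from-scratch merge cost -----------------------------------------------

## The greedy ranking criterion for merging columns j, jp of `cols`,
## recomputed by brute force (for the beta losses: build the full distance
## matrices before and after the candidate merge).
oracle_pair_cost <- function(loss, cols, j, jp, tree = NULL, leaf_of = NULL) {
  u <- cols[, j]; v <- cols[, jp]
  merged <- cols
  merged[, j] <- u + v
  merged <- merged[, -jp, drop = FALSE]
  if (loss == "sdi") return(sum(u * v))
  if (loss == "swi") {
    f <- function(x) sum(ifelse(x > 0, x * log(x), 0))
    return(f(u + v) - f(u) - f(v))
  }
  if (loss == "bc") {
    D0 <- oracle_bc_dist(cols)
    D1 <- oracle_bc_dist(merged)
    return(sum((D0[upper.tri(D0)] - D1[upper.tri(D1)])^2))
  }
  # wuf step criterion: only the merged pair's terms are replaced, with the
  # new entity's branch lengths read off an actually reduced tree copy
  l0 <- unname(tree$edge_length[leaf_of])
  L0 <- vapply(leaf_of, function(id) oracle_root_path(tree, id), 0)
  D0 <- oracle_wuf_dist(cols, l0, L0)
  tr2 <- reduce_tree(tree, leaf_of[j], leaf_of[jp], label = "..merge..")
  new_leaf <- attr(tr2, "new_leaf")
  l1 <- l0; L1 <- L0
  l1[j] <- unname(tr2$edge_length[new_leaf])
  L1[j] <- oracle_root_path(tr2, new_leaf)
  l1 <- l1[-jp]; L1 <- L1[-jp]
  D1 <- oracle_wuf_dist(merged, l1, L1)
  sum((D0[upper.tri(D0)] - D1[upper.tri(D1)])^2)
}

## Replay a fitted path step by step, calling `check(t, cols, tree, leaf_of,
## j, jp)` on the state *before* each recorded merge.
replay_path <- function(path, check) {
  cols <- unclass(path$X)
  labels <- path$taxon_ids
  tree <- path$taxonomy
  leaf_of <- if (!is.null(tree))
    vapply(path$taxon_ids, function(tx) taxon_node(tree, tx), 0L, USE.NAMES = FALSE)
  for (t in seq_len(path$p - 1L)) {
    j <- match(path$steps$left[t], labels)
    jp <- match(path$steps$right[t], labels)
    stopifnot(!is.na(j), !is.na(jp), j < jp)
    res <- check(t, cols, tree, leaf_of, j, jp)
    if (identical(res, FALSE)) return(invisible(FALSE))
    if (is.list(res) && !is.null(res$tree)) tree <- res$tree
    cols[, j] <- cols[, j] + cols[, jp]
    cols <- cols[, -jp, drop = FALSE]
    if (!is.null(tree)) {
      tree <- reduce_tree(tree, leaf_of[j], leaf_of[jp],
                          label = path$steps$label[t])
      leaf_of[j] <- attr(tree, "new_leaf")
      leaf_of <- leaf_of[-jp]
    }
    labels[j] <- path$steps$label[t]
    labels <- labels[-jp]
  }
  invisible(TRUE)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
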