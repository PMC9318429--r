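#' Active merge candidates under a hierarchy mode
#'
#' Returns the pairs of current columns that may legally be amalgamated at
#' this step. With `mode = "none"` all column pairs are candidates. Under the
#' weak taxonomic hierarchy only pairs sharing their lowest multi-child
#' ancestor in the current reduced tree qualify; the strong hierarchy further
#' requires both members to sit at the current maximum leaf depth, so taxa at
#' the lowest rank are always aggregated first.
#'
#' @param tree Current reduced `taxonomy_tree` (may be `NULL` for
#'   `mode = "none"`).
#' @param leaf_of Integer vector mapping current columns to tree leaf ids.
#' @param m Number of current columns.
#' @param mode `"none"`, `"weak"` or `"strong"`.
#' @return 2-by-npairs integer matrix of column index pairs (j < j'), in
#'   lexicographic order. May have zero columns in strong mode when no two
#'   deepest leaves share an ancestor (the runner then applies its fallbacks).
#' @export
active_pairs <- function(tree, leaf_of, m, mode = c("none", "weak", "strong")) {
  mode <- match.arg(mode)
  if (m < 2L) return(matrix(integer(0), 2L, 0L))
  if (mode == "none") return(all_pairs(m))
  if (is.null(tree)) stop("hierarchy mode '", mode, "' requires a taxonomy")
  astar <- vapply(leaf_of, function(id) lowest_multichild_ancestor(tree, id), 0L)
  keep <- seq_len(m)
  if (mode == "strong") {
    depth <- vapply(leaf_of, function(id) node_depth(tree, id), 0L)
    keep <- which(depth == max(depth))
  }
  pairs_within_groups(astar, keep)
}

all_pairs <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  t(idx[ord, , drop = FALSE])
}

pairs_within_groups <- function(group, keep) {
  out <- lapply(split(keep, group[keep]), function(members) {
    if (length(members) < 2L) return(NULL)
    members <- sort(members)
    all_pairs_of(members)
  })
  pairs <- do.call(cbind, c(out, list(matrix(integer(0), 2L, 0L))))
  if (ncol(pairs)) pairs[, order(pairs[1, ], pairs[2, ]), drop = FALSE] else pairs
}

all_pairs_of <- function(members) {
  cmb <- utils::combn(members, 2L)
  cmb
}

#' Hierarchical principal amalgamation analysis
#'
#' Greedy agglomerative amalgamation of a compositional data matrix: starting
#' from the p original taxa, at every step the pair of current columns whose
#' merge loses the least information (under the chosen diversity loss) is
#' summed, until a single all-ones column remains. The full path of p-1
#' simple amalgamations is returned and can be cut at any number of principal
#' compositions with [cut()].
#'
#' When a taxonomy is supplied the merges can be confined to it: under the
#' weak hierarchy only taxa sharing their lowest multi-child ancestor may
#' merge; under the strong hierarchy merges are further restricted to the
#' current deepest rank. Tree reduction is coupled to the merges: merged taxa
#' are replaced by a single leaf and emptied or unary internal nodes are
#' collapsed. If in strong mode a lone deepest taxon has no eligible partner,
#' its unary parent chain is collapsed first (raising it one rank); if an
#' eligible pair still does not exist, that step falls back to the weak rule
#' among groups containing a deepest taxon.
#'
#' The algorithm is fully deterministic: cost ties are broken by the
#' lexicographically smallest pair of current column indices.
#'
#' @param X Composition matrix, or count/abundance matrix with
#'   `normalize = TRUE`.
#' @param taxonomy A `taxonomy_tree` whose leaves match `colnames(X)`.
#'   Required for the weak/strong hierarchies and for the `"wuf"` loss.
#' @param loss Information loss: `"sdi"` (Simpson), `"swi"` (Shannon),
#'   `"bc"` (Bray-Curtis distortion) or `"wuf"` (weighted UniFrac
#'   distortion).
#' @param hierarchy `"none"` (synonym `"unconstrained"`), `"weak"` or
#'   `"strong"`.
#' @param normalize Close rows to relative abundances first.
#' @param pseudocount Optional zero replacement applied before a `"swi"` run
#'   (zeros become `pseudocount`, rows are re-closed). By default the
#'   `0 log 0 = 0` convention is used instead and no replacement is needed.
#' @return A `merge_path` object: a list with the hclust-style `merge`
#'   matrix, a `steps` data frame (per-step and cumulative losses, merged
#'   labels, k after the step), the original data and taxonomy, and for
#'   lineage-derived taxonomies the rank-crossing annotations.
#' @examples
#' X <- composition_matrix(rbind(c(.6, .3, .1), c(.2, .3, .5)))
#' path <- run_hpaa(X, loss = "sdi")
#' path$steps
#' cut(path, k = 2)$scores
#' @export
run_hpaa <- function(X, taxonomy = NULL,
                     loss = c("sdi", "swi", "bc", "wuf"),
                     hierarchy = c("none", "weak", "strong"),
                     normalize = FALSE, pseudocount = NULL) {
  loss <- match.arg(loss)
  hierarchy <- match.arg(hierarchy[1], c("none", "unconstrained", "weak", "strong"))
  if (hierarchy == "unconstrained") hierarchy <- "none"
  X <- composition_matrix(X, normalize = normalize)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("need at least two taxa to amalgamate")
  if (is.null(taxonomy)) {
    if (hierarchy != "none") stop("hierarchy '", hierarchy, "' requires a taxonomy")
    if (loss == "wuf") stop("loss 'wuf' requires a taxonomy")
  } else {
    if (!inherits(taxonomy, "taxonomy_tree")) stop("'taxonomy' must be a taxonomy_tree")
    if (!setequal(names(tree_leaves(taxonomy)), colnames(X)))
      stop("tree leaves do not match the taxa of X")
  }
  if (!is.null(pseudocount)) {
    if (loss != "swi") warning("pseudocount is only used by the 'swi' loss")
    Xm <- unclass(X); Xm[Xm == 0] <- pseudocount
    X <- composition_matrix(Xm / rowSums(Xm), rownames(X), colnames(X))
  }

  taxon_ids <- colnames(X)
  cols <- unclass(X)
  tree <- taxonomy
  leaf_of <- if (!is.null(tree))
    vapply(taxon_ids, function(tx) taxon_node(tree, tx), 0L, USE.NAMES = FALSE)
  state <- loss_state_init(loss, cols, tree, leaf_of)

  # cumulative-loss reference quantities on the original data
  alpha0 <- if (loss %in% c("sdi", "swi")) total_alpha(loss, X)
  if (loss %in% c("bc", "wuf")) {
    B0 <- if (loss == "bc") bc_matrix(cols) else state$W
    beta_denom <- sum(B0[upper.tri(B0)]^2)
    B <- B0
  }

  node_of <- -seq_len(p)           # hclust convention: negatives = taxa
  labels <- taxon_ids
  merge <- matrix(0L, p - 1L, 2L)
  steps <- data.frame(step = seq_len(p - 1L), k = (p - 1L):1L,
                      left = character(p - 1L), right = character(p - 1L),
                      label = character(p - 1L),
                      step_loss = numeric(p - 1L),
                      cum_loss = numeric(p - 1L),
                      cum_pct_loss = numeric(p - 1L),
                      stringsAsFactors = FALSE)
  length_trace <- if (loss == "wuf") vector("list", p)
  if (loss == "wuf") length_trace[[1]] <- list(l = state$l, L = state$L)
  cum <- 0

  for (t in seq_len(p - 1L)) {
    m <- ncol(cols)
    sel <- select_pair(loss, state, cols, tree, leaf_of, m, hierarchy)
    tree <- sel$tree                     # strong mode may have collapsed ranks
    j <- sel$pair[1]; jp <- sel$pair[2]; cost <- sel$cost

    new_label <- paste0(labels[j], "+", labels[jp])
    merge[t, ] <- sort(c(node_of[j], node_of[jp]))
    steps$left[t] <- labels[j]; steps$right[t] <- labels[jp]
    steps$label[t] <- new_label

    # apply the merge to the matrix and the tree
    cols[, j] <- cols[, j] + cols[, jp]
    cols <- cols[, -jp, drop = FALSE]
    colnames(cols)[j] <- new_label
    if (!is.null(tree)) {
      tree <- reduce_tree(tree, leaf_of[j], leaf_of[jp], label = new_label)
      leaf_of[j] <- attr(tree, "new_leaf")
      leaf_of <- leaf_of[-jp]
    }
    node_of[j] <- t; node_of <- node_of[-jp]
    labels[j] <- new_label; labels <- labels[-jp]
    state <- loss_state_update(loss, state, j, jp, cols, tree, leaf_of)

    # loss bookkeeping
    if (loss %in% c("sdi", "swi")) {
      drop <- max(0, if (loss == "sdi") 2 * cost else cost)
      cum <- cum + drop
      steps$step_loss[t] <- drop
      steps$cum_loss[t] <- cum
      steps$cum_pct_loss[t] <- if (alpha0 > 0) 100 * cum / alpha0 else 0
    } else {
      B <- if (loss == "bc") bc_matrix(cols) else state$W
      steps$step_loss[t] <- cost
      dev <- sum((B0[upper.tri(B0)] - B[upper.tri(B)])^2)
      steps$cum_loss[t] <- dev
      steps$cum_pct_loss[t] <- if (beta_denom > 0) 100 * dev / beta_denom else 0
    }
    if (loss == "wuf") length_trace[[t + 1L]] <- list(l = state$l, L = state$L)
  }

  path <- structure(list(
    merge = merge, steps = steps, taxon_ids = taxon_ids,
    loss = loss, hierarchy = hierarchy, n = n, p = p,
    X = X, taxonomy = taxonomy,
    alpha0 = if (loss %in% c("sdi", "swi")) alpha0,
    beta_denom = if (loss %in% c("bc", "wuf")) beta_denom,
    length_trace = if (loss == "wuf") length_trace,
    rank_crossings = NULL), class = "merge_path")
  path$rank_crossings <- rank_crossings(path)
  path
}

bc_matrix <- function(cols) as.matrix(stats::dist(cols, method = "manhattan")) / 2

## One greedy selection, including the strong-mode fallbacks. Returns the
## chosen pair (current column indices, j < j'), its cost, and the (possibly
## rank-collapsed) tree.
select_pair <- function(loss, state, cols, tree, leaf_of, m, hierarchy) {
  tree_before <- tree
  pairs <- active_pairs(tree, leaf_of, m, hierarchy)
  if (hierarchy == "strong" && ncol(pairs) == 0L) {
    repeat {
      depth <- vapply(leaf_of, function(id) node_depth(tree, id), 0L)
      deepest <- leaf_of[depth == max(depth)]
      tree <- collapse_unary_parents(tree, deepest)
      changed <- isTRUE(attr(tree, "changed"))
      pairs <- active_pairs(tree, leaf_of, m, "strong")
      if (ncol(pairs) > 0L || !changed) break
    }
    if (ncol(pairs) == 0L) {
      # weak rule restricted to ancestor groups holding a deepest taxon
      astar <- vapply(leaf_of, function(id) lowest_multichild_ancestor(tree, id), 0L)
      depth <- vapply(leaf_of, function(id) node_depth(tree, id), 0L)
      grp_has_deep <- astar %in% astar[depth == max(depth)]
      pairs <- pairs_within_groups(astar, which(grp_has_deep))
    }
    if (ncol(pairs) == 0L) {
      deepest <- which.max(vapply(leaf_of, function(id) node_depth(tree, id), 0L))
      stop("strong hierarchy deadlock: no eligible partner for node '",
           tree$label[leaf_of[deepest]], "'")
    }
  }
  if (!identical(tree, tree_before) && loss == "wuf")
    state <- wuf_state(cols, tree, leaf_of)
  costs <- loss_costs(loss, state, pairs, cols, tree, leaf_of)
  best <- which(costs == min(costs))[1]  # pairs are in lexicographic order
  list(pair = pairs[, best], cost = costs[best], tree = tree,
       tree_before = tree_before)
}

#' Compose a merge path into an amalgamation matrix
#'
#' Replays the first `p - k` merges of the path and returns the resulting
#' partition of the original taxa as an [amalgamation_matrix()]. Groups are
#' numbered by their smallest member taxon index.
#'
#' @param path A `merge_path` from [run_hpaa()].
#' @param k Number of groups to keep, `1 <= k <= p`.
#' @return An `amalgamation_matrix` with `k` groups.
#' @export
compose_path <- function(path, k) {
  stopifnot(inherits(path, "merge_path"))
  p <- path$p
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > p)
    stop("k must lie in 1..", p)
  k <- as.integer(k)
  members <- vector("list", p - 1L)
  assignment <- seq_len(p)  # group key: taxon index, or p + last forming step
  for (t in seq_len(p - k)) {
    a <- path$merge[t, 1]; b <- path$merge[t, 2]
    ma <- if (a < 0) -a else members[[a]]
    mb <- if (b < 0) -b else members[[b]]
    members[[t]] <- c(ma, mb)
    assignment[members[[t]]] <- p + t
  }
  first <- tapply(seq_len(p), assignment, min)   # smallest member per group
  key <- as.numeric(names(first))
  rank_of <- integer(length(key))
  rank_of[order(first)] <- seq_along(key)        # groups numbered by first member
  grp <- rank_of[match(assignment, key)]
  labs <- character(length(key))
  labs[rank_of] <- ifelse(key <= p, path$taxon_ids[pmin(key, p)],
                          path$steps$label[pmax(key - p, 1L)])
  amalgamation_matrix(grp, k = k, group_ids = labs, taxon_ids = path$taxon_ids)
}

#' Cut a merge path at k principal compositions
#'
#' @param x A `merge_path`.
#' @param k Number of principal compositions to keep.
#' @param X Data to score; defaults to the matrix the path was fitted on.
#' @param ... Unused.
#' @return A list with the loading matrix `R` (an `amalgamation_matrix`), the
#'   `scores` composition matrix (n by k), and `loss_report` holding the
#'   cumulative loss and percentage loss at this cut.
#' @export
cut.merge_path <- function(x, k, X = x$X, ...) {
  R <- compose_path(x, k)
  if (is.null(X)) stop("the path carries no data; supply X")
  scores <- amalgamate(X, R)
  t_cut <- x$p - as.integer(k)
  report <- list(loss = x$loss, hierarchy = x$hierarchy, k = as.integer(k),
                 cum_loss = if (t_cut == 0L) 0 else x$steps$cum_loss[t_cut],
                 cum_pct_loss = if (t_cut == 0L) 0 else x$steps$cum_pct_loss[t_cut])
  list(R = R, scores = scores, loss_report = report)
}

## Rank-crossing annotations for lineage-derived taxonomies: for every named
## rank, the step at which the path first reaches as many groups as the rank
## has categories, and whether the partition matches those categories.
rank_crossings <- function(path) {
  tree <- path$taxonomy
  if (is.null(tree) || is.null(tree$lineages)) return(NULL)
  lin <- tree$lineages[path$taxon_ids, , drop = FALSE]
  out <- lapply(seq_along(lin), function(d) {
    cat <- lin[[d]]
    cat[is.na(cat)] <- paste0("<leaf>", which(is.na(cat)))  # unclassified stay alone
    g <- length(unique(cat))
    if (g >= path$p || g < 1L) return(NULL)
    t_cross <- path$p - g
    part <- compose_path(path, g)$assignment
    exact <- all(tapply(cat, part, function(z) length(unique(z)) == 1L))
    data.frame(rank = names(lin)[d], depth = d, k = g, step = t_cross,
               height = path$steps$cum_pct_loss[t_cross], exact = exact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(out) && nrow(out)) out else NULL
}

#' @export
print.merge_path <- function(x, ...) {
  cat("HPAA merge path: ", x$p, " taxa, ", x$n, " samples, loss = ", x$loss,
      ", hierarchy = ", x$hierarchy, "\n", sep = "")
  cat("total steps: ", x$p - 1L, "; final cumulative loss ",
      format(x$steps$cum_pct_loss[x$p - 1L], digits = 4), "%\n", sep = "")
  invisible(x)
}

#' Serialize a merge path as a dendrogram in Newick format
#'
#' Branch lengths are differences in cumulative percentage loss between
#' consecutive merges, so external viewers reproduce the dendrogram heights.
#'
#' @param path A `merge_path`.
#' @return A Newick string.
#' @export
path_to_newick <- function(path) {
  height <- c(0, path$steps$cum_pct_loss)
  rec <- function(node) {
    if (node < 0) return(list(str = newick_quote(path$taxon_ids[-node]), h = 0))
    a <- rec(path$merge[node, 1]); b <- rec(path$merge[node, 2])
    h <- height[node + 1L]
    list(str = paste0("(", a$str, ":", format(h - a$h, digits = 10), ",",
                      b$str, ":", format(h - b$h, digits = 10), ")"), h = h)
  }
  paste0(rec(path$p - 1L)$str, ";")
}
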