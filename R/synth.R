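#' Specification for synthetic microbiome data
#'
#' Bundles the generator parameters. Defaults emulate a genus-level gut
#' microbiome profile: a few dozen samples, tens of taxa on a six-rank
#' taxonomy with unary chains (taxa classified at different ranks), planted
#' taxon groups, and roughly 40% zero entries.
#'
#' @param n_samples Number of samples.
#' @param n_taxa Number of taxa (tree leaves); at least 2.
#' @param tree_depth Maximum leaf depth of the simulated taxonomy.
#' @param min_children,max_children Child-count range when a node branches.
#' @param unary_prob Probability of inserting a unary (single-child) rank
#'   node, producing a non-complete tree.
#' @param groups Number of planted taxon groups `g`.
#' @param group_alpha Dirichlet concentration of the per-sample group
#'   weights.
#' @param within_alpha Dirichlet concentration of the within-group splits.
#' @param zero_inflation Probability of masking an entry to zero (rows are
#'   re-closed afterwards); in `[0, 1)`.
#' @param seed Integer seed (base R Mersenne-Twister RNG).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 50L, n_taxa = 60L, tree_depth = 6L,
                       min_children = 2L, max_children = 4L, unary_prob = 0.15,
                       groups = 5L, group_alpha = 1, within_alpha = 0.8,
                       zero_inflation = 0.4, seed = 1L) {
  stopifnot(n_samples >= 1L, n_taxa >= 2L, tree_depth >= 1L,
            min_children >= 2L, max_children >= min_children,
            unary_prob >= 0, unary_prob < 1,
            groups >= 1L, groups <= n_taxa,
            group_alpha > 0, within_alpha > 0,
            zero_inflation >= 0, zero_inflation < 1)
  if (max_children^tree_depth < n_taxa)
    stop("a depth-", tree_depth, " tree with at most ", max_children,
         " children per node cannot reach ", n_taxa, " leaves")
  structure(list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
                 tree_depth = as.integer(tree_depth),
                 min_children = as.integer(min_children),
                 max_children = as.integer(max_children),
                 unary_prob = unary_prob, groups = as.integer(groups),
                 group_alpha = group_alpha, within_alpha = within_alpha,
                 zero_inflation = zero_inflation, seed = as.integer(seed)),
            class = "synth_spec")
}

rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  while (sum(g) == 0) g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a taxonomy tree
#'
#' Grows a rooted tree to exactly `n_taxa` leaves by repeatedly splitting a
#' random expandable leaf slot; with probability `unary_prob` a slot first
#' grows a unary rank node, so leaves end up at different depths
#' (non-complete classification). Lineage metadata is attached so rank
#' annotations and color bars work on simulated data.
#'
#' @param spec A [synth_spec()].
#' @return A unit-edge-length `taxonomy_tree` with leaves `T1..Tp` (numbered
#'   in left-to-right tree order).
#' @export
simulate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  p <- spec$n_taxa
  # grow a nested list of leaf slots; each slot records its depth
  slots <- data.frame(id = 1L, parent = NA_integer_, depth = 0L)
  nleaf <- function() sum(!slots$id %in% slots$parent)
  mc <- spec$max_children
  # capacity: how many leaves the current slots can still produce; every
  # action keeps capacity >= p so growth can never strand below n_taxa
  capacity <- function() {
    leaves <- slots$id[!slots$id %in% slots$parent]
    sum(mc^(spec$tree_depth - slots$depth[match(leaves, slots$id)]))
  }
  nxt <- 2L
  while (nleaf() < p) {
    leaves <- slots$id[!slots$id %in% slots$parent]
    expandable <- leaves[slots$depth[match(leaves, slots$id)] < spec$tree_depth]
    if (!length(expandable)) stop("tree growth exhausted before reaching n_taxa")
    pick <- expandable[sample.int(length(expandable), 1L)]
    d <- slots$depth[match(pick, slots$id)]
    room <- spec$tree_depth - d
    cap <- capacity()
    if (stats::runif(1) < spec$unary_prob && room >= 2L &&
        cap - mc^room + mc^(room - 1L) >= p) {
      slots <- rbind(slots, data.frame(id = nxt, parent = pick, depth = d + 1L))
      nxt <- nxt + 1L
      next
    }
    need <- p - nleaf()
    kids <- sample(seq(spec$min_children, mc), 1L)
    kids <- min(kids, need + 1L)
    # bump the child count up if a smaller family would sink capacity below p
    while (kids < min(mc, need + 1L) && cap - mc^room + kids * mc^(room - 1L) < p)
      kids <- kids + 1L
    if (cap - mc^room + kids * mc^(room - 1L) < p) next  # try another slot
    slots <- rbind(slots, data.frame(id = nxt + seq_len(kids) - 1L, parent = pick,
                                     depth = d + 1L))
    nxt <- nxt + kids
  }
  # convert to lineage strings, naming leaves T1..Tp in id order
  leaves <- slots$id[!slots$id %in% slots$parent]
  leaves <- sort(leaves)
  lineages <- vapply(seq_along(leaves), function(i) {
    node <- leaves[i]
    chain <- character(0)
    while (!is.na(node)) {
      chain <- c(paste0("N", node), chain)
      node <- slots$parent[match(node, slots$id)]
    }
    chain <- chain[-1]                       # drop the root
    chain[length(chain)] <- paste0("T", i)   # leaf field is the taxon id
    paste(chain, collapse = ";")
  }, "")
  tree_from_lineages(lineages)
}

#' Simulate compositional abundance data
#'
#' Each sample draws Dirichlet weights over `g` planted taxon groups
#' (contiguous blocks of leaves in tree order) and splits each group's weight
#' among its taxa by a within-group Dirichlet; entries are then masked to
#' zero independently with probability `zero_inflation` and rows re-closed
#' (a fully masked sample is redrawn).
#'
#' With `disjoint_support = TRUE` a sharper design is generated for
#' structure-recovery experiments: every sample carries mass on exactly one
#' taxon per group, so taxa within a group never co-occur (their columns have
#' disjoint support) while taxa from different groups do. No zero masking is
#' applied in this mode.
#'
#' @param spec A [synth_spec()].
#' @param tree Taxonomy from [simulate_taxonomy()] (its leaves define the
#'   taxa; defaults to simulating one from `spec`).
#' @param disjoint_support Use the disjoint-support construction.
#' @return A list with the `composition_matrix` `X` and the integer
#'   `true_partition` of the taxa into the planted groups.
#' @export
simulate_compositions <- function(spec, tree = NULL, disjoint_support = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(tree)) tree <- simulate_taxonomy(spec)
  taxa <- names(tree_leaves(tree))
  ord <- order(as.integer(sub("^T", "", taxa)))
  taxa <- taxa[ord]
  p <- length(taxa)
  if (p != spec$n_taxa) stop("tree has ", p, " leaves but spec$n_taxa = ", spec$n_taxa)
  n <- spec$n_samples; g <- spec$groups
  truth <- sort(rep_len(seq_len(g), p))      # contiguous blocks in taxon order
  set.seed(spec$seed + 1L)
  X <- matrix(0, n, p, dimnames = list(paste0("S", seq_len(n)), taxa))
  # disjoint mode: balanced (shuffled round-robin) selection of the active
  # taxon per group, so every taxon is expressed in at least one sample
  # whenever n_samples >= group size
  picks <- if (disjoint_support)
    lapply(seq_len(g), function(b) {
      len <- sum(truth == b)
      rep_len(seq_len(len), n)[sample.int(n)]
    })
  for (i in seq_len(n)) {
    for (attempt in seq_len(100L)) {
      w <- rdirichlet_row(rep(spec$group_alpha, g))
      x <- numeric(p)
      for (b in seq_len(g)) {
        idx <- which(truth == b)
        if (disjoint_support) {
          x[idx[picks[[b]][i]]] <- w[b]
        } else {
          x[idx] <- w[b] * rdirichlet_row(rep(spec$within_alpha, length(idx)))
        }
      }
      if (!disjoint_support && spec$zero_inflation > 0)
        x[stats::runif(p) < spec$zero_inflation] <- 0
      if (sum(x) > 0) break
      x <- NULL
    }
    if (is.null(x)) stop("sample ", i, " was masked to zero in 100 attempts")
    X[i, ] <- x / sum(x)
  }
  list(X = composition_matrix(X), true_partition = truth)
}

#' Small worked-example taxonomy
#'
#' A compact non-complete taxonomy exercising the tree queries the hierarchy
#' modes rely on: `Taxon 1` sits directly under the root (depth 1) while
#' `Taxon 2` and `Taxon 3` are depth-5 siblings; `Taxon 13` hangs below a
#' unary rank node so its lowest multi-child ancestor is its grandparent,
#' shared with `Taxon 12`; `Taxon 26` and `Taxon 27` sit under different
#' multi-child ancestors.
#'
#' @return A unit-edge-length `taxonomy_tree` with 8 leaves.
#' @export
example_taxonomy <- function() {
  tree_from_lineages(c(
    "Taxon 1",
    "F1;F2;F3;F4;Taxon 2",
    "F1;F2;F3;F4;Taxon 3",
    "F1;G2;Taxon 12",
    "F1;G2;U1;Taxon 13",
    "F1;H1;Taxon 26",
    "F1;H1;Taxon 28",
    "F1;H2;Taxon 27"))
}
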