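#' Taxonomic trees
#'
#' A `taxonomy_tree` is a rooted tree whose leaves map one-to-one onto the
#' current taxa. The tree may be *non-complete*: taxa classified at different
#' ranks sit at different depths, and unary chains (internal nodes with a
#' single child) are legal and preserved. Every edge carries a strictly
#' positive length (1 for rank-based taxonomies).
#'
#' Internally the tree is a set of parallel vectors indexed by stable integer
#' node ids; nodes removed during tree reduction are deactivated, and merged
#' leaves receive fresh ids, so a merge path can be replayed unambiguously.
#'
#' @name taxonomy_tree
#' @keywords internal
NULL

new_taxonomy_tree <- function(parent, edge_length, label, taxon, active, root,
                              unit_lengths, lineages = NULL) {
  nchild <- tabulate(parent[active & !is.na(parent)], nbins = length(parent))
  structure(list(parent = parent, edge_length = edge_length, label = label,
                 taxon = taxon, active = active, nchild = nchild, root = root,
                 unit_lengths = unit_lengths, lineages = lineages),
            class = "taxonomy_tree")
}

node_ids <- function(tree) which(tree$active)

#' Leaf nodes of a taxonomy tree
#'
#' @param tree A `taxonomy_tree`.
#' @return Integer node ids of the active leaves, named by their taxon ids.
#' @export
tree_leaves <- function(tree) {
  ids <- which(tree$active & tree$nchild == 0L)
  names(ids) <- tree$taxon[ids]
  ids
}

#' Look up the leaf node carrying a taxon
#' @param tree A `taxonomy_tree`.
#' @param taxon_id Taxon identifier.
#' @return Integer node id.
#' @export
taxon_node <- function(tree, taxon_id) {
  id <- which(tree$active & !is.na(tree$taxon) & tree$taxon == taxon_id)
  if (length(id) != 1L) stop("taxon '", taxon_id, "' not found in tree")
  id
}

check_node <- function(tree, node) {
  if (!is.numeric(node) || length(node) != 1L || node < 1 ||
      node > length(tree$parent) || !tree$active[node])
    stop("unknown node id: ", node)
  as.integer(node)
}

#' Depth of a node
#'
#' The number of ancestors between the node and the root; the root itself has
#' depth 0.
#'
#' @param tree A `taxonomy_tree`.
#' @param node Integer node id.
#' @return Non-negative integer depth.
#' @export
node_depth <- function(tree, node) {
  node <- check_node(tree, node)
  d <- 0L
  while (!is.na(tree$parent[node])) {
    node <- tree$parent[node]
    d <- d + 1L
  }
  d
}

#' Depth of a tree
#'
#' Maximum depth over the leaves.
#' @param tree A `taxonomy_tree`.
#' @return Integer.
#' @export
tree_depth <- function(tree) max(vapply(tree_leaves(tree), node_depth, 0L, tree = tree))

#' Root-to-node path length
#'
#' Sum of edge lengths from the root down to `node`.
#' @param tree A `taxonomy_tree`.
#' @param node Integer node id.
#' @return Numeric path length (0 for the root).
#' @export
root_path_length <- function(tree, node) {
  node <- check_node(tree, node)
  len <- 0
  while (!is.na(tree$parent[node])) {
    len <- len + tree$edge_length[node]
    node <- tree$parent[node]
  }
  len
}

#' Lowest multi-child ancestor of a leaf
#'
#' The nearest ancestor of `leaf` having more than one child. Unary chains
#' above a leaf are skipped, so two leaves separated only by unary nodes share
#' their lowest multi-child ancestor.
#'
#' @param tree A `taxonomy_tree`.
#' @param leaf Integer id of a leaf node.
#' @return Integer node id of the ancestor.
#' @export
lowest_multichild_ancestor <- function(tree, leaf) {
  leaf <- check_node(tree, leaf)
  if (tree$nchild[leaf] > 0L) stop("node ", leaf, " is not a leaf")
  node <- tree$parent[leaf]
  while (!is.na(node)) {
    if (tree$nchild[node] > 1L) return(node)
    node <- tree$parent[node]
  }
  stop("leaf ", leaf, " has no multi-child ancestor (single-leaf tree)")
}

lowest_common_ancestor <- function(tree, a, b) {
  anc <- a
  node <- a
  while (!is.na(tree$parent[node])) { node <- tree$parent[node]; anc <- c(anc, node) }
  node <- b
  while (!(node %in% anc)) node <- tree$parent[node]
  node
}

children_of <- function(tree, node) which(tree$active & !is.na(tree$parent) & tree$parent == node)

## Collapse a unary internal node into its single child: the child's edge
## absorbs the parent's edge length, preserving all root-to-leaf path lengths.
collapse_single <- function(tree, node) {
  stopifnot(tree$nchild[node] == 1L, !is.na(tree$parent[node]))
  child <- children_of(tree, node)
  gp <- tree$parent[node]
  tree$edge_length[child] <- tree$edge_length[child] + tree$edge_length[node]
  tree$parent[child] <- gp
  tree$active[node] <- FALSE
  tree$parent[node] <- NA_integer_
  tree$nchild[node] <- 0L
  tree
}

## Remove a leaf and prune the now-childless or unary ancestors above it,
## stopping at `keep` (the attachment node of a merge) and at the root.
prune_upwards <- function(tree, node, keep) {
  while (!is.na(node) && node != tree$root && node != keep) {
    up <- tree$parent[node]
    if (tree$nchild[node] == 0L && is.na(tree$taxon[node])) {
      tree$active[node] <- FALSE
      tree$parent[node] <- NA_integer_
      tree$nchild[up] <- tree$nchild[up] - 1L
    } else if (tree$nchild[node] == 1L) {
      tree <- collapse_single(tree, node)
    } else break
    node <- up
  }
  tree
}

#' Expected branch lengths of a pairwise merge
#'
#' Computes, without modifying the tree, the branch length `l` and
#' root-path length `L` that the leaf formed by merging `a` and `b` would
#' receive under [reduce_tree()]. Used when scoring candidate merges for the
#' weighted UniFrac loss.
#'
#' @param tree A `taxonomy_tree`.
#' @param a,b Integer ids of two distinct leaves.
#' @return Named numeric vector `c(l = ..., L = ...)`.
#' @export
merge_branch_lengths <- function(tree, a, b) {
  a <- check_node(tree, a); b <- check_node(tree, b)
  att <- merge_attachment(tree, a, b)
  l <- if (tree$unit_lengths) 1 else min(tree$edge_length[a], tree$edge_length[b])
  L <- root_path_length(tree, att) + l
  # if the attachment would be left unary (removing the two leaves empties
  # all its other branches) the new leaf absorbs the attachment's edge on
  # collapse; a branch only empties when the leaf's whole chain up to the
  # attachment is unary
  removed <- chain_removed(tree, att, a) + chain_removed(tree, att, b)
  if (tree$nchild[att] == removed && att != tree$root)
    l <- l + tree$edge_length[att]
  c(l = l, L = L)
}

## TRUE when removing `leaf` leaves nothing on its child-of-att branch
chain_removed <- function(tree, att, leaf) {
  node <- leaf
  while (tree$parent[node] != att) {
    node <- tree$parent[node]
    if (tree$nchild[node] > 1L) return(FALSE)
  }
  TRUE
}

merge_attachment <- function(tree, a, b) {
  asa <- lowest_multichild_ancestor(tree, a)
  asb <- lowest_multichild_ancestor(tree, b)
  if (asa == asb) asa else lowest_common_ancestor(tree, a, b)
}

#' Reduce a taxonomy tree by merging two leaves
#'
#' Removes leaves `a` and `b` and inserts a single new leaf representing the
#' amalgamated taxon. The new leaf attaches below the shared lowest
#' multi-child ancestor of the pair when one exists, otherwise below their
#' lowest common ancestor. Its edge length is 1 for rank-based (unit-length)
#' taxonomies and the minimum of the two replaced edge lengths otherwise.
#' Internal nodes left childless are removed and unary chains created by the
#' removal are collapsed (edge lengths summed), which realizes the
#' aggregation of a last remaining taxon to a higher rank.
#'
#' @param tree A `taxonomy_tree`.
#' @param a,b Integer ids of two distinct leaves.
#' @param label Display label for the new leaf; defaults to `"<a>+<b>"`.
#' @param taxon Taxon id carried by the new leaf (defaults to `label`).
#' @return The reduced tree, with the id of the new leaf in attribute
#'   `"new_leaf"`.
#' @export
reduce_tree <- function(tree, a, b, label = NULL, taxon = NULL) {
  a <- check_node(tree, a); b <- check_node(tree, b)
  if (a == b) stop("cannot merge a leaf with itself")
  if (tree$nchild[a] > 0L || tree$nchild[b] > 0L) stop("both nodes must be leaves")
  if (is.null(label)) label <- paste0(tree$label[a], "+", tree$label[b])
  if (is.null(taxon)) taxon <- label
  att <- merge_attachment(tree, a, b)
  lnew <- if (tree$unit_lengths) 1 else min(tree$edge_length[a], tree$edge_length[b])

  pa <- tree$parent[a]; pb <- tree$parent[b]
  for (leaf in c(a, b)) {
    up <- tree$parent[leaf]
    tree$active[leaf] <- FALSE
    tree$taxon[leaf] <- NA_character_
    tree$parent[leaf] <- NA_integer_
    tree$nchild[up] <- tree$nchild[up] - 1L
  }

  # fresh id for the merged leaf
  id <- length(tree$parent) + 1L
  tree$parent[id] <- att
  tree$edge_length[id] <- lnew
  tree$label[id] <- label
  tree$taxon[id] <- taxon
  tree$active[id] <- TRUE
  tree$nchild[id] <- 0L
  tree$nchild[att] <- tree$nchild[att] + 1L

  # clean up the vacated chains, then the attachment itself if it went unary
  tree <- prune_upwards(tree, pa, keep = att)
  tree <- prune_upwards(tree, pb, keep = att)
  if (tree$nchild[att] == 1L && att != tree$root && tree$active[att])
    tree <- collapse_single(tree, att)
  attr(tree, "new_leaf") <- id
  tree
}

## Collapse the unary parent chains directly above the given leaves (used by
## the strong hierarchy mode to let a stranded deepest taxon rise one rank).
collapse_unary_parents <- function(tree, leaves) {
  changed <- FALSE
  for (leaf in leaves) {
    par <- tree$parent[leaf]
    if (!is.na(par) && par != tree$root && tree$nchild[par] == 1L) {
      tree <- collapse_single(tree, par)
      changed <- TRUE
    }
  }
  attr(tree, "changed") <- changed
  tree
}

#' Build a taxonomy tree from lineage strings
#'
#' Parses QIIME/greengenes-style rank lineages, one per taxon, e.g.
#' `"Bacteria;Proteobacteria;Gammaproteobacteria"`. The final field names the
#' taxon itself; shared prefixes become shared internal nodes, so taxa
#' classified at different ranks yield leaves at different depths
#' (a non-complete tree). All edges get unit length.
#'
#' @param lineages Character vector of lineage strings.
#' @param taxon_ids Taxon identifiers; default the last lineage field.
#' @param sep Field separator within a lineage (default `";"`).
#' @param strip_rank_prefix Drop greengenes rank prefixes such as `"g__"`.
#' @return A `taxonomy_tree` with `p = length(lineages)` leaves. The parsed
#'   per-taxon rank table is retained in `$lineages` for rank annotations.
#' @examples
#' tr <- tree_from_lineages(c("A;B;C1", "A;B;C2", "A;D"))
#' node_depth(tr, taxon_node(tr, "C1"))
#' @export
tree_from_lineages <- function(lineages, taxon_ids = NULL, sep = ";",
                               strip_rank_prefix = FALSE) {
  if (length(lineages) < 1L) stop("no lineages given")
  fields <- strsplit(trimws(lineages), sep, fixed = TRUE)
  fields <- lapply(fields, trimws)
  if (strip_rank_prefix)
    fields <- lapply(fields, function(f) sub("^[a-zA-Z]__", "", f))
  if (any(vapply(fields, function(f) any(!nzchar(f)), TRUE)))
    stop("lineage with an empty rank field (mid-lineage gap)")
  if (is.null(taxon_ids))
    taxon_ids <- vapply(fields, function(f) f[length(f)], "")
  if (anyDuplicated(taxon_ids))
    stop("duplicated taxon labels: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))

  parent <- NA_integer_; edge <- NA_real_; label <- "root"; taxon <- NA_character_
  path_id <- new.env(parent = emptyenv())  # full lineage prefix -> node id
  nnode <- 1L
  for (i in seq_along(fields)) {
    cur <- 1L
    f <- fields[[i]]
    for (d in seq_along(f)) {
      key <- paste(f[seq_len(d)], collapse = "\x1f")
      id <- path_id[[key]]
      if (is.null(id)) {
        nnode <- nnode + 1L
        id <- nnode
        parent[id] <- cur
        edge[id] <- 1
        label[id] <- f[d]
        taxon[id] <- NA_character_
        path_id[[key]] <- id
      }
      cur <- id
    }
    if (!is.na(taxon[cur]))
      stop("two taxa share the identical lineage: ", lineages[i])
    taxon[cur] <- taxon_ids[i]
  }
  tree <- new_taxonomy_tree(parent, edge, label, taxon, active = rep(TRUE, nnode),
                            root = 1L, unit_lengths = TRUE,
                            lineages = lineage_table(fields, taxon_ids))
  bad <- which(tree$active & tree$nchild > 0L & !is.na(tree$taxon))
  if (length(bad))
    stop("lineage of taxon '", tree$taxon[bad[1]],
         "' is a prefix of another taxon's lineage")
  tree
}

lineage_table <- function(fields, taxon_ids) {
  depth <- max(lengths(fields))
  tab <- matrix(NA_character_, length(fields), depth,
                dimnames = list(taxon_ids, paste0("rank", seq_len(depth))))
  for (i in seq_along(fields)) tab[i, seq_along(fields[[i]])] <- fields[[i]]
  as.data.frame(tab, stringsAsFactors = FALSE)
}

#' Convert an ape phylo object to a taxonomy tree
#'
#' Singleton (unary) internal nodes, as produced by `ape::read.tree()` on
#' non-complete taxonomies, are preserved. Missing edge lengths default to 1.
#'
#' @param phy An [ape::read.tree()] `phylo` object; must be rooted.
#' @param unit_lengths Treat the tree as a rank-based unit-length taxonomy
#'   (newly merged leaves get edge length 1). Default `FALSE`: merged leaves
#'   inherit the minimum of the replaced edge lengths.
#' @return A `taxonomy_tree` whose leaves carry the tip labels as taxon ids.
#' @export
as_taxonomy_tree <- function(phy, unit_lengths = FALSE) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (length(setdiff(phy$edge[, 1], phy$edge[, 2])) != 1L)
    stop("tree must have a single root")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  parent <- rep(NA_integer_, nnode)
  edge <- rep(NA_real_, nnode)
  len <- if (is.null(phy$edge.length)) rep(1, nrow(phy$edge)) else phy$edge.length
  if (any(len <= 0)) stop("edge lengths must be strictly positive")
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  edge[phy$edge[, 2]] <- len
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  tips <- newick_unquote(phy$tip.label)
  label <- c(tips,
             if (is.null(phy$node.label)) paste0("N", seq_len(phy$Nnode))
             else newick_unquote(phy$node.label))
  taxon <- c(tips, rep(NA_character_, phy$Nnode))
  if (anyDuplicated(tips)) stop("duplicated tip labels")
  new_taxonomy_tree(parent, edge, label, taxon, active = rep(TRUE, nnode),
                    root = as.integer(root), unit_lengths = unit_lengths)
}

#' Serialize a taxonomy tree to a Newick string
#'
#' @param tree A `taxonomy_tree`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (with trailing `;`).
#' @export
taxonomy_to_newick <- function(tree, digits = 10) {
  rec <- function(node) {
    kids <- children_of(tree, node)
    lab <- newick_quote(if (!is.na(tree$taxon[node])) tree$taxon[node] else tree$label[node])
    body <- if (length(kids) == 0L) lab
            else paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")",
                        if (node == tree$root) "" else lab)
    if (is.na(tree$parent[node])) body
    else paste0(body, ":", format(tree$edge_length[node], digits = digits))
  }
  paste0(rec(tree$root), ";")
}

newick_quote <- function(x) {
  if (grepl("[][ ():,;']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

newick_unquote <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Branch lengths of the current leaves
#'
#' For each taxon (in the given order) returns the leaf branch length `l` and
#' the root-to-leaf path length `L`, the two quantities entering the weighted
#' UniFrac distance.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_ids Order of taxa; defaults to the tree's leaf order.
#' @return A list with numeric vectors `l` and `L`.
#' @export
leaf_branch_lengths <- function(tree, taxon_ids = NULL) {
  leaves <- tree_leaves(tree)
  if (!is.null(taxon_ids)) {
    if (!setequal(taxon_ids, names(leaves)))
      stop("taxon_ids do not match the tree's leaves")
    leaves <- leaves[taxon_ids]
  }
  list(l = unname(tree$edge_length[leaves]),
       L = vapply(leaves, root_path_length, 0, tree = tree, USE.NAMES = FALSE))
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  leaves <- tree_leaves(x)
  cat("Taxonomy tree: ", length(leaves), " leaves, ",
      length(node_ids(x)), " nodes, depth ", tree_depth(x),
      if (x$unit_lengths) ", unit edge lengths" else "", "\n", sep = "")
  invisible(x)
}
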