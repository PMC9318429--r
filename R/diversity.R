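#' Simpson's diversity index
#'
#' `1 - sum(x^2)`: the probability that two individuals drawn at random from
#' the sample belong to different taxa. Lies in `[0, 1)`; 0 when a single
#' taxon holds all mass.
#'
#' @param x Composition vector (non-negative, summing to 1).
#' @return Numeric scalar.
#' @export
simpson_index <- function(x) {
  check_simplex(x)
  1 - sum(x^2)
}

#' Shannon-Wiener index
#'
#' `-sum(x * log(x))` with natural logarithm and the continuity convention
#' `0 * log(0) = 0`, so sparse compositions need no zero replacement. Equally
#' sensitive to rare and dominant taxa; maximal (`log p`) for the uniform
#' composition.
#'
#' @param x Composition vector.
#' @return Numeric scalar `>= 0`.
#' @export
shannon_index <- function(x) {
  check_simplex(x)
  -sum(xlogx(x))
}

xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

#' Bray-Curtis dissimilarity
#'
#' For compositions (unit-sum vectors) Bray-Curtis reduces to half the
#' Manhattan distance: `1 - sum(pmin(x, y)) = sum(abs(x - y)) / 2`.
#'
#' @param x,y Composition vectors of equal length.
#' @return Numeric scalar in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  check_simplex(x); check_simplex(y)
  1 - sum(pmin(x, y))
}

#' Weighted UniFrac distance
#'
#' Tree-aware between-sample distance
#' `sum(l_j * abs(x_j - y_j)) / sum(L_j * (x_j + y_j))`, where `l_j` is the
#' branch length of the leaf carrying taxon j and `L_j` its root-to-leaf path
#' length. Symmetric, zero iff the two compositions coincide, and bounded by
#' 1 (since `l_j <= L_j`).
#'
#' @param x,y Composition vectors, ordered as `taxon_ids`.
#' @param tree A `taxonomy_tree` whose leaves are the taxa.
#' @param taxon_ids Taxon order of `x`/`y`; defaults to the tree leaf order.
#' @return Numeric scalar in `[0, 1]`.
#' @export
weighted_unifrac <- function(x, y, tree, taxon_ids = NULL) {
  if (missing(tree) || !inherits(tree, "taxonomy_tree"))
    stop("weighted UniFrac requires a taxonomy_tree")
  if (length(x) != length(y)) stop("length mismatch")
  check_simplex(x); check_simplex(y)
  bl <- leaf_branch_lengths(tree, taxon_ids)
  if (length(bl$l) != length(x)) stop("composition length does not match tree leaves")
  wuf_from_lengths(x, y, bl$l, bl$L)
}

wuf_from_lengths <- function(x, y, l, L) {
  den <- sum(L * (x + y))
  if (den == 0) return(0)
  sum(l * abs(x - y)) / den
}

check_simplex <- function(x, tol = 1e-6) {
  if (any(x < 0)) stop("negative entries in composition vector")
  if (abs(sum(x) - 1) > tol) stop("composition vector does not sum to 1")
  invisible(x)
}

#' Total alpha diversity of a composition matrix
#'
#' Sum over samples of the chosen within-sample diversity index. The
#' alpha-type amalgamation loss is the decrease of this total.
#'
#' @param loss `"sdi"` or `"swi"`.
#' @param X Composition matrix (samples by taxa).
#' @return Numeric scalar.
#' @export
total_alpha <- function(loss = c("sdi", "swi"), X) {
  loss <- match.arg(loss)
  X <- unclass(X)
  switch(loss,
         sdi = sum(1 - rowSums(X^2)),
         swi = -sum(xlogx(X)))
}

#' Between-sample distance matrix
#'
#' @param loss `"bc"` or `"wuf"`.
#' @param X Composition matrix.
#' @param tree Required for `"wuf"`.
#' @param taxon_ids Taxon order for `"wuf"`; defaults to `colnames(X)`.
#' @return Symmetric n-by-n matrix of pairwise distances.
#' @export
beta_distances <- function(loss = c("bc", "wuf"), X, tree = NULL, taxon_ids = colnames(X)) {
  loss <- match.arg(loss)
  X <- unclass(X)
  n <- nrow(X)
  if (loss == "bc") {
    D <- as.matrix(stats::dist(X, method = "manhattan")) / 2
  } else {
    if (is.null(tree)) stop("weighted UniFrac requires a taxonomy_tree")
    bl <- leaf_branch_lengths(tree, taxon_ids)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- wuf_from_lengths(X[i, ], X[j, ], bl$l, bl$L)
  }
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Cumulative beta-diversity distortion of an amalgamation
#'
#' Sum over sample pairs of the squared difference between the original
#' pairwise distance and the distance after amalgamating with `R`. This is
#' the quantity the beta-type losses accumulate along a merge path.
#'
#' @param loss `"bc"` or `"wuf"`.
#' @param X Original composition matrix.
#' @param R An [amalgamation_matrix()].
#' @param tree Original taxonomy (for `"wuf"`); the reduced tree for the
#'   amalgamated data is obtained by replaying the merges, see
#'   [run_hpaa()]. When `tree_after` is `NULL` the amalgamated distances are
#'   computed as Bray-Curtis for `"bc"` and require `tree_after` for `"wuf"`.
#' @param tree_after Reduced taxonomy matching the amalgamated data (for
#'   `"wuf"`).
#' @return Numeric scalar `>= 0`.
#' @export
beta_distortion <- function(loss = c("bc", "wuf"), X, R, tree = NULL, tree_after = NULL) {
  loss <- match.arg(loss)
  Y <- amalgamate(X, R)
  D0 <- beta_distances(loss, X, tree, colnames(X))
  D1 <- if (loss == "bc") beta_distances("bc", Y)
        else beta_distances("wuf", Y, tree_after, colnames(Y))
  sum((D0[upper.tri(D0)] - D1[upper.tri(D1)])^2)
}
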