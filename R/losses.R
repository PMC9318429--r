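## Loss machinery for the greedy amalgamation step.
##
## Each loss pairs a total-information measure over the current amalgamated
## matrix with a pair-merge cost: the ranking criterion minimized at each
## step of the hierarchical algorithm.
##   sdi: inner product of the two columns (realized SDI drop is twice this;
##        the Gram matrix of the current data is cached and updated in O(m)
##        per merge, since only two columns change).
##   swi: sum over samples of (a+b)log(a+b) - a log a - b log b.
##   bc : sum over sample pairs of the squared change in the shared-minimum
##        term of the Bray-Curtis distance.
##   wuf: sum over sample pairs of the squared change in weighted UniFrac,
##        with the merged leaf's branch lengths taken from the coupled tree
##        reduction.

#' Pair-merge cost of a candidate amalgamation
#'
#' The ranking criterion the greedy algorithm minimizes when deciding which
#' two columns of the current matrix to amalgamate. For `"sdi"` this is the
#' inner product of the two columns (the realized drop in total Simpson
#' diversity is twice the value); for `"swi"` it equals the realized drop in
#' total Shannon diversity; for `"bc"` and `"wuf"` it is the stepwise
#' distortion of the pairwise distance matrix of the *current* data.
#'
#' @param loss One of `"sdi"`, `"swi"`, `"bc"`, `"wuf"`.
#' @param X Current (possibly already amalgamated) composition matrix.
#' @param j,jp Distinct column indices of the candidate pair.
#' @param tree Current reduced `taxonomy_tree` (required for `"wuf"`), whose
#'   leaves are the columns of `X` (matched via `colnames(X)`).
#' @return Non-negative numeric cost.
#' @export
pair_cost <- function(loss = c("sdi", "swi", "bc", "wuf"), X, j, jp, tree = NULL) {
  loss <- match.arg(loss)
  if (j == jp) stop("candidate pair must be two distinct columns")
  X <- unclass(X)
  u <- X[, j]; v <- X[, jp]
  switch(loss,
    sdi = sum(u * v),
    swi = swi_pair_cost(u, v),
    bc = bc_pair_cost(u, v),
    wuf = {
      if (is.null(tree)) stop("loss 'wuf' requires a taxonomy_tree")
      leaf_of <- vapply(colnames(X), function(tx) taxon_node(tree, tx), 0L)
      st <- wuf_state(X, tree, leaf_of)
      wuf_costs(st, rbind(j, jp), X, tree, leaf_of)
    })
}

swi_pair_cost <- function(u, v) {
  max(0, sum(xlogx(u + v)) - sum(xlogx(u)) - sum(xlogx(v)))
}

pmin_outer <- function(x) outer(x, x, pmin)

bc_pair_cost <- function(u, v) {
  if (length(u) < 2L) return(0)
  d <- pmin_outer(u) + pmin_outer(v) - pmin_outer(u + v)
  sum(d[upper.tri(d)]^2)
}

## ---- incremental state ----------------------------------------------------

loss_state_init <- function(loss, cols, tree, leaf_of) {
  switch(loss,
    sdi = list(G = crossprod(cols)),
    swi = list(C = pairwise_cost_matrix(cols, swi_pair_cost)),
    bc = list(C = pairwise_cost_matrix(cols, bc_pair_cost)),
    wuf = wuf_state(cols, tree, leaf_of))
}

pairwise_cost_matrix <- function(cols, fun) {
  m <- ncol(cols)
  C <- matrix(Inf, m, m)
  if (m > 1L)
    for (j in seq_len(m - 1L)) for (jp in (j + 1L):m)
      C[j, jp] <- C[jp, j] <- fun(cols[, j], cols[, jp])
  C
}

loss_costs <- function(loss, state, pairs, cols, tree, leaf_of) {
  if (loss == "sdi") return(state$G[t(pairs)])
  if (loss %in% c("swi", "bc")) return(state$C[t(pairs)])
  wuf_costs(state, pairs, cols, tree, leaf_of)
}

## `cols_new`, `tree_new`, `leaf_of_new` describe the state after the merge:
## column j holds the summed pair, column jp has been dropped.
loss_state_update <- function(loss, state, j, jp, cols_new, tree_new, leaf_of_new) {
  if (loss == "sdi") {
    G <- state$G
    g <- G[, j] + G[, jp]
    gjj <- G[j, j] + 2 * G[j, jp] + G[jp, jp]
    G[j, ] <- g; G[, j] <- g; G[j, j] <- gjj
    return(list(G = G[-jp, -jp, drop = FALSE]))
  }
  if (loss %in% c("swi", "bc")) {
    fun <- if (loss == "swi") swi_pair_cost else bc_pair_cost
    C <- state$C[-jp, -jp, drop = FALSE]
    m <- ncol(cols_new)
    newj <- vapply(seq_len(m), function(i)
      if (i == j) Inf else fun(cols_new[, j], cols_new[, i]), 0)
    C[j, ] <- newj; C[, j] <- newj
    return(list(C = C))
  }
  wuf_state(cols_new, tree_new, leaf_of_new)
}

## Weighted UniFrac bookkeeping: per-column leaf branch length l and
## root-path length L, plus the numerator and denominator matrices of the
## current pairwise WUF distances. Rebuilt from the reduced tree after every
## merge because a merge (or a strong-mode rank collapse) can change branch
## lengths beyond the merged pair.
wuf_state <- function(cols, tree, leaf_of) {
  if (is.null(tree)) stop("loss 'wuf' requires a taxonomy_tree")
  n <- nrow(cols); m <- ncol(cols)
  l <- unname(tree$edge_length[leaf_of])
  L <- vapply(leaf_of, root_path_length, 0, tree = tree, USE.NAMES = FALSE)
  N <- matrix(0, n, n); Dn <- matrix(0, n, n)
  for (j in seq_len(m)) {
    x <- cols[, j]
    N <- N + l[j] * abs(outer(x, x, "-"))
    Dn <- Dn + L[j] * outer(x, x, "+")
  }
  list(l = l, L = L, N = N, Dn = Dn, W = safe_div(N, Dn))
}

safe_div <- function(a, b) {
  out <- a / b
  out[b == 0] <- 0
  out
}

wuf_costs <- function(state, pairs, cols, tree, leaf_of) {
  ut <- upper.tri(state$W)
  apply(pairs, 2, function(pr) {
    j <- pr[1]; jp <- pr[2]
    u <- cols[, j]; v <- cols[, jp]
    lw <- merge_branch_lengths(tree, leaf_of[j], leaf_of[jp])
    s <- u + v
    N2 <- state$N - state$l[j] * abs(outer(u, u, "-")) -
      state$l[jp] * abs(outer(v, v, "-")) + lw[["l"]] * abs(outer(s, s, "-"))
    D2 <- state$Dn - state$L[j] * outer(u, u, "+") -
      state$L[jp] * outer(v, v, "+") + lw[["L"]] * outer(s, s, "+")
    sum((state$W[ut] - safe_div(N2, D2)[ut])^2)
  })
}
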