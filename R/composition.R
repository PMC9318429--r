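#' Construct a composition matrix
#'
#' Validates (and optionally closes) a samples-by-taxa relative abundance
#' matrix. Every row of a composition matrix lies in the simplex: entries are
#' non-negative and each row sums to one. Raw count tables can be converted
#' with `normalize = TRUE`, which divides each row by its total.
#'
#' @param values Numeric matrix (or data frame) with samples as rows and taxa
#'   as columns.
#' @param sample_ids,taxon_ids Unique row/column identifiers. Default to the
#'   dimnames of `values`, or `S1..Sn` / `T1..Tp` when absent.
#' @param normalize If `TRUE`, rows are divided by their sums (count tables).
#'   Rows summing to zero are an error.
#' @param tol Tolerance for the unit row-sum check when `normalize = FALSE`.
#' @return A numeric matrix of class `composition_matrix` with dimnames set.
#' @examples
#' X <- composition_matrix(rbind(c(2, 3, 5), c(1, 1, 2)), normalize = TRUE)
#' rowSums(X)
#' @export
composition_matrix <- function(values, sample_ids = NULL, taxon_ids = NULL,
                               normalize = FALSE, tol = 1e-8) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  n <- nrow(values); p <- ncol(values)
  if (n < 1L || p < 1L) stop("composition matrix must have at least one row and column")
  if (anyNA(values)) stop("composition matrix contains missing values")
  if (any(values < 0)) stop("composition matrix contains negative entries")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(taxon_ids)) taxon_ids <- colnames(values)
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(p))
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(taxon_ids)) stop("duplicated taxon ids")
  if (length(sample_ids) != n || length(taxon_ids) != p)
    stop("id lengths do not match matrix dimensions")
  rs <- rowSums(values)
  if (normalize) {
    if (any(rs == 0))
      stop("cannot normalize: sample(s) ",
           paste(sample_ids[rs == 0], collapse = ", "), " have zero total")
    values <- values / rs
  } else if (any(abs(rs - 1) > tol)) {
    stop("row sums deviate from 1 by more than ", tol,
         "; use normalize = TRUE for count tables")
  }
  dimnames(values) <- list(sample_ids, taxon_ids)
  class(values) <- c("composition_matrix", class(values))
  values
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("Composition matrix: ", nrow(x), " samples x ", ncol(x), " taxa\n", sep = "")
  y <- x
  class(y) <- setdiff(class(y), "composition_matrix")
  print(utils::head(y, 6L), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more samples)\n", sep = "")
  invisible(x)
}

#' Construct an amalgamation (loading) matrix
#'
#' An amalgamation matrix is a binary k-by-p matrix whose columns each sum to
#' exactly one: it encodes a partition of the p taxa into k groups (some of
#' which may be empty). It is stored compactly as the length-p assignment
#' vector; use [as.matrix()] for the binary form.
#'
#' @param assignment Integer vector of length p mapping each taxon to a group
#'   index in `1..k`.
#' @param k Number of groups. Defaults to `max(assignment)`.
#' @param group_ids Optional k group labels.
#' @param taxon_ids Optional p taxon labels.
#' @return An object of class `amalgamation_matrix`.
#' @examples
#' R <- amalgamation_matrix(c(1, 1, 2, 3, 3))
#' as.matrix(R)
#' @export
amalgamation_matrix <- function(assignment, k = max(assignment),
                                group_ids = NULL, taxon_ids = NULL) {
  assignment <- as.integer(assignment)
  p <- length(assignment)
  if (p < 1L) stop("empty assignment")
  if (anyNA(assignment)) stop("assignment contains missing values")
  if (any(assignment < 1L) || any(assignment > k))
    stop("assignment values must lie in 1..k")
  if (k < 1L || k > p) stop("k must satisfy 1 <= k <= p")
  if (is.null(group_ids)) group_ids <- paste0("PC", seq_len(k))
  if (length(group_ids) != k) stop("group_ids must have length k")
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(p))
  if (length(taxon_ids) != p) stop("taxon_ids must have length p")
  structure(list(assignment = assignment, k = as.integer(k), p = p,
                 group_ids = group_ids, taxon_ids = taxon_ids),
            class = "amalgamation_matrix")
}

#' @export
as.matrix.amalgamation_matrix <- function(x, ...) {
  R <- matrix(0, x$k, x$p, dimnames = list(x$group_ids, x$taxon_ids))
  R[cbind(x$assignment, seq_len(x$p))] <- 1
  R
}

#' @export
print.amalgamation_matrix <- function(x, ...) {
  cat("Amalgamation matrix: ", x$p, " taxa -> ", x$k, " groups\n", sep = "")
  sizes <- tabulate(x$assignment, nbins = x$k)
  cat("group sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Amalgamate a composition matrix
#'
#' Applies an amalgamation matrix to the data: the columns of `X` assigned to
#' the same group are summed, producing the n-by-k score matrix. Row sums
#' (total mass) are conserved exactly.
#'
#' @param X Composition matrix (samples by taxa).
#' @param R An [amalgamation_matrix()] with `R$p == ncol(X)`.
#' @return An n-by-k `composition_matrix` of principal compositions.
#' @examples
#' X <- composition_matrix(matrix(c(.1, .2, .3, .25, .15), 1))
#' amalgamate(X, amalgamation_matrix(c(1, 1, 2, 3, 3)))
#' @export
amalgamate <- function(X, R) {
  if (!inherits(R, "amalgamation_matrix")) stop("'R' must be an amalgamation_matrix")
  if (ncol(X) != R$p)
    stop("assignment length (", R$p, ") does not match number of taxa (", ncol(X), ")")
  Xm <- unclass(X)
  # rowsum() on the transpose groups taxa; keeps empty groups absent, so
  # build explicitly to honour all k group slots
  Y <- matrix(0, nrow(Xm), R$k, dimnames = list(rownames(Xm), R$group_ids))
  agg <- rowsum(t(Xm), group = R$assignment)
  Y[, as.integer(rownames(agg))] <- t(agg)
  composition_matrix(Y, sample_ids = rownames(Xm) %||% paste0("S", seq_len(nrow(Xm))),
                     taxon_ids = R$group_ids, tol = 1e-6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
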