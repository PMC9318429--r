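#' Read an abundance table
#'
#' Reads a delimited text table (TSV by default; comma is autodetected from
#' the file extension or the header line) with sample and taxon identifiers
#' in the header row and first column. Values must be non-negative numbers;
#' count tables can be closed to relative abundances with `normalize = TRUE`.
#'
#' @param path File path.
#' @param orientation `"samples_rows"` (default) or `"taxa_rows"` for
#'   transposed files.
#' @param normalize Close rows to relative abundances.
#' @param sep Field separator; autodetected when `NULL`.
#' @return A [composition_matrix()].
#' @export
read_composition <- function(path, orientation = c("samples_rows", "taxa_rows"),
                             normalize = FALSE, sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- sep %||% sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  ids <- as.character(tab[[1]])
  tab <- tab[, -1, drop = FALSE]
  if (anyDuplicated(ids)) stop("duplicated row identifiers in ", path)
  if (anyDuplicated(colnames(tab))) stop("duplicated column identifiers in ", path)
  num <- vapply(tab, is.numeric, TRUE)
  if (!all(num))
    stop("non-numeric values in column(s): ", paste(colnames(tab)[!num], collapse = ", "))
  M <- as.matrix(tab)
  rownames(M) <- ids
  if (orientation == "taxa_rows") M <- t(M)
  composition_matrix(M, normalize = normalize)
}

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  header <- readLines(path, n = 1L)
  if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
}

#' Write a composition matrix to a delimited file
#'
#' Numbers are written with `%.17g`, so reading the file back reproduces the
#' doubles bit-exactly.
#'
#' @param X Composition (or any numeric) matrix with dimnames.
#' @param path Output path; `.csv` selects comma separation, otherwise TSV.
#' @param sep Field separator; autodetected from the extension when `NULL`.
#' @export
write_composition <- function(X, path, sep = NULL) {
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  M <- unclass(X)
  fmt <- matrix(sprintf("%.17g", M), nrow(M), dimnames = dimnames(M))
  out <- cbind(id = rownames(M), fmt)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = c("id", colnames(M)))
  invisible(path)
}

#' Read a lineage table and build the taxonomy
#'
#' The file has one taxon per line: either a single column of lineage strings
#' (the last field names the taxon) or two delimited columns
#' `taxon<TAB>lineage`. Lineage fields are `;`-separated,
#' QIIME/greengenes-style; rank prefixes such as `g__` can be stripped.
#'
#' @param path File path.
#' @param sep Column separator of the file (default tab).
#' @param lineage_sep Separator within a lineage string (default `";"`).
#' @param strip_rank_prefix Strip greengenes `x__` prefixes.
#' @return A `taxonomy_tree` (see [tree_from_lineages()]).
#' @export
read_lineages <- function(path, sep = "\t", lineage_sep = ";",
                          strip_rank_prefix = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(parts)
  if (all(ncols >= 2L)) {
    taxa <- vapply(parts, `[[`, "", 1L)
    lin <- vapply(parts, `[[`, "", 2L)
    tree_from_lineages(lin, taxon_ids = taxa, sep = lineage_sep,
                       strip_rank_prefix = strip_rank_prefix)
  } else {
    tree_from_lineages(lines, sep = lineage_sep,
                       strip_rank_prefix = strip_rank_prefix)
  }
}

#' Read a taxonomy from a Newick file
#'
#' @param path Newick file (or a literal Newick string containing `";"`).
#' @param unit_lengths See [as_taxonomy_tree()].
#' @return A `taxonomy_tree`.
#' @export
read_taxonomy <- function(path, unit_lengths = FALSE) {
  phy <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
         else ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick input")
  as_taxonomy_tree(phy, unit_lengths = unit_lengths)
}

#' Serialize a merge path to JSON
#'
#' Records everything needed to replay the path (merge table, labels, taxon
#' order, per-step and cumulative losses, loss and hierarchy settings);
#' [read_path_json()] reconstructs a `merge_path` that [compose_path()] and
#' [cut()] accept (supply the data matrix to `cut()` for scores).
#'
#' @param path A `merge_path`.
#' @param file Output path; when `NULL` the JSON string is returned.
#' @return `file` (invisibly), or the JSON string.
#' @export
path_to_json <- function(path, file = NULL) {
  obj <- list(loss = path$loss, hierarchy = path$hierarchy,
              n = path$n, p = path$p, taxon_ids = path$taxon_ids,
              merge = path$merge, steps = path$steps,
              rank_crossings = path$rank_crossings)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}

#' Read a merge path from JSON
#'
#' @param file Path to a file written by [path_to_json()].
#' @return A `merge_path` without the fitted data matrix (`$X` is `NULL`).
#' @export
read_path_json <- function(file) {
  obj <- jsonlite::fromJSON(file)
  structure(list(merge = matrix(as.integer(obj$merge), ncol = 2L),
                 steps = as.data.frame(obj$steps),
                 taxon_ids = as.character(obj$taxon_ids),
                 loss = obj$loss, hierarchy = obj$hierarchy,
                 n = as.integer(obj$n), p = as.integer(obj$p),
                 X = NULL, taxonomy = NULL,
                 rank_crossings = if (!is.null(obj$rank_crossings))
                   as.data.frame(obj$rank_crossings)),
            class = "merge_path")
}

#' Write the standard outputs of an amalgamation
#'
#' Writes four artifacts sharing a path prefix: the binary loading matrix
#' (`<prefix>_loadings.tsv`, taxa by groups), the score matrix
#' (`<prefix>_scores.tsv`), the merge path (`<prefix>_path.json`) and the
#' dendrogram (`<prefix>_dendrogram.nwk`).
#'
#' @param prefix Output path prefix.
#' @param R An `amalgamation_matrix`.
#' @param scores The matching score matrix.
#' @param path The `merge_path` (optional; skips the JSON/Newick artifacts
#'   when `NULL`).
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(prefix, R, scores, path = NULL) {
  files <- character(0)
  loadings <- t(as.matrix(R))          # taxa x groups, 0/1
  f <- paste0(prefix, "_loadings.tsv")
  out <- cbind(taxon = rownames(loadings),
               matrix(as.character(loadings), nrow(loadings),
                      dimnames = dimnames(loadings)))
  utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- paste0(prefix, "_scores.tsv")
  write_composition(scores, f)
  files <- c(files, f)
  if (!is.null(path)) {
    f <- paste0(prefix, "_path.json")
    path_to_json(path, f)
    files <- c(files, f)
    f <- paste0(prefix, "_dendrogram.nwk")
    writeLines(path_to_newick(path), f)
    files <- c(files, f)
  }
  invisible(files)
}
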