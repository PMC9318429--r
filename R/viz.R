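#' Convert a merge path to an hclust object
#'
#' Heights are the cumulative percentage information loss, which is
#' non-decreasing along the path, so standard dendrogram tooling applies.
#'
#' @param x A `merge_path`.
#' @param ... Unused.
#' @return A `stats::hclust` object.
#' @exportS3Method stats::as.hclust
as.hclust.merge_path <- function(x, ...) {
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) { ord <<- c(ord, -node); return(invisible()) }
    walk(x$merge[node, 1]); walk(x$merge[node, 2])
  }
  walk(x$p - 1L)
  structure(list(merge = x$merge, height = x$steps$cum_pct_loss, order = ord,
                 labels = x$taxon_ids, method = paste0("hpaa-", x$loss),
                 call = match.call(), dist.method = x$loss),
            class = "hclust")
}

dendrogram_segments <- function(path) {
  hc <- stats::as.hclust(path)
  pos <- numeric(path$p)                       # leaf x positions
  pos[hc$order] <- seq_len(path$p)
  xc <- numeric(path$p - 1L)                   # x center of each merge node
  segs <- vector("list", path$p - 1L)
  for (t in seq_len(path$p - 1L)) {
    ab <- path$merge[t, ]
    xx <- ifelse(ab < 0, pos[-pmin(ab, -1L)], xc[pmax(ab, 1L)])
    hh <- ifelse(ab < 0, 0, path$steps$cum_pct_loss[pmax(ab, 1L)])
    h <- path$steps$cum_pct_loss[t]
    xc[t] <- mean(xx)
    segs[[t]] <- data.frame(
      x = c(xx[1], xx[2], xx[1]), xend = c(xx[1], xx[2], xx[2]),
      y = c(hh[1], hh[2], h), yend = c(h, h, h))
  }
  do.call(rbind, segs)
}

#' Amalgamation dendrogram
#'
#' Draws the merge path as a dendrogram whose merge heights are the
#' cumulative percentage loss of the chosen diversity measure, so a
#' horizontal cut at any height shows the principal compositions obtainable
#' at that loss. For alpha-diversity losses the height axis is log-scaled by
#' default (zero heights are floored at half the smallest positive height).
#' Rank-crossing guides (steps at which the data could be aggregated to a
#' named taxonomic rank) are drawn as red dashed lines, and per-rank color
#' bars are stacked under the leaves when lineage metadata is available.
#'
#' @param path A `merge_path`.
#' @param lineages Per-taxon rank table (rows = taxa); defaults to the
#'   lineage metadata carried by the path's taxonomy, if any.
#' @param log_scale Log-scale the loss axis; default `TRUE` for `sdi`/`swi`.
#' @param cut_k Optionally draw the horizontal cut giving `k` groups.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(path, lineages = NULL, log_scale = NULL, cut_k = NULL) {
  stopifnot(inherits(path, "merge_path"))
  if (is.null(lineages) && !is.null(path$taxonomy)) lineages <- path$taxonomy$lineages
  if (is.null(log_scale)) log_scale <- path$loss %in% c("sdi", "swi")
  segs <- dendrogram_segments(path)
  h <- path$steps$cum_pct_loss
  if (log_scale && all(h == 0)) {
    warning("all merge heights are zero; falling back to a linear axis")
    log_scale <- FALSE
  }
  floor_h <- if (log_scale) min(h[h > 0]) / 2 else 0
  if (log_scale) {
    segs$y <- pmax(segs$y, floor_h)
    segs$yend <- pmax(segs$yend, floor_h)
  }
  hc <- stats::as.hclust(path)
  g <- ggplot2::ggplot() +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend),
                          data = segs, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = paste0("cumulative ", toupper(path$loss),
                                       " loss (%)")) +
    ggplot2::scale_x_continuous(breaks = seq_len(path$p),
                                labels = path$taxon_ids[hc$order],
                                expand = ggplot2::expansion(add = 0.6)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6),
                   panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (!is.null(path$rank_crossings)) {
    ch <- pmax(path$rank_crossings$height, floor_h)
    g <- g + ggplot2::geom_hline(yintercept = ch, colour = "red",
                                 linetype = "dashed", linewidth = 0.3)
  }
  if (!is.null(cut_k)) {
    t_cut <- path$p - cut_k
    hcut <- if (t_cut < 1L) floor_h
            else if (t_cut >= path$p - 1L) max(h)
            else sqrt(pmax(h[t_cut], floor_h) * pmax(h[t_cut + 1L], floor_h))
    g <- g + ggplot2::geom_hline(yintercept = max(hcut, floor_h),
                                 colour = "blue", linewidth = 0.4)
  }
  if (!is.null(lineages)) {
    lineages <- lineages[path$taxon_ids, , drop = FALSE]
    span <- max(h[h > 0], 1)
    nr <- ncol(lineages)
    bars <- do.call(rbind, lapply(seq_len(nr), function(d) {
      cat <- lineages[[d]]
      cat[is.na(cat)] <- "unclassified"
      data.frame(x = seq_len(path$p), rank = names(lineages)[d], ri = d,
                 category = cat[hc$order], stringsAsFactors = FALSE)
    }))
    if (log_scale) {
      bars$y <- floor_h * 0.85^(bars$ri - 1) * 0.85 / 2
      bars$h <- floor_h * (0.85^(bars$ri - 1) - 0.85^bars$ri)
    } else {
      bars$y <- -span * (0.03 * bars$ri - 0.015)
      bars$h <- span * 0.028
    }
    g <- g + ggplot2::geom_tile(ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$category,
                                             height = .data$h),
                                data = bars, show.legend = FALSE)
  }
  if (log_scale) g <- g + ggplot2::scale_y_log10()
  g
}

#' Scree plot of cumulative information loss
#'
#' One curve per merge path: cumulative percentage loss (relative to the
#' original data) against the number of principal compositions k, from p
#' down to 1.
#'
#' @param paths A `merge_path` or a list of them sharing the same loss.
#' @return A ggplot object.
#' @export
plot_scree <- function(paths) {
  if (inherits(paths, "merge_path")) paths <- list(paths)
  losses <- unique(vapply(paths, `[[`, "", "loss"))
  if (length(losses) > 1L)
    stop("all paths in one scree plot must share the loss (found: ",
         paste(losses, collapse = ", "), ")")
  dat <- do.call(rbind, lapply(paths, function(pa) {
    data.frame(k = c(pa$p, pa$steps$k), pct = c(0, pa$steps$cum_pct_loss),
               hierarchy = pa$hierarchy, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k, y = .data$pct,
                                    colour = .data$hierarchy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "number of principal compositions",
                  y = paste0("cumulative ", toupper(losses), " loss (%)"),
                  colour = "hierarchy") +
    ggplot2::theme_minimal()
}

#' Lift principal compositions back to taxon space
#'
#' Distributes each group's mass over its member taxa in proportion to the
#' taxa's mean relative abundances in the original data (equal split when a
#' group carries no mass anywhere), which makes Bray-Curtis between original
#' samples and principal compositions well defined and is exact at `k = p`.
#'
#' @param X Original composition matrix.
#' @param R The `amalgamation_matrix` of the cut.
#' @param scores The score matrix; recomputed from `X` and `R` when `NULL`.
#' @return An n-by-p composition matrix.
#' @export
lift_scores <- function(X, R, scores = NULL) {
  if (is.null(scores)) scores <- amalgamate(X, R)
  w <- colMeans(unclass(X))
  p <- R$p
  lifted <- matrix(0, nrow(X), p, dimnames = dimnames(unclass(X)))
  for (gr in seq_len(R$k)) {
    idx <- which(R$assignment == gr)
    if (!length(idx)) next
    wg <- w[idx]
    wg <- if (sum(wg) > 0) wg / sum(wg) else rep(1 / length(idx), length(idx))
    lifted[, idx] <- unclass(scores)[, gr] %o% wg
  }
  composition_matrix(lifted, tol = 1e-6)
}

#' NMDS ordination of original and amalgamated samples
#'
#' Runs 2-D non-metric multidimensional scaling (Bray-Curtis, monotone
#' stress-1 via [vegan::metaMDS()], at least 16 random starts, fixed seed)
#' on the original samples pooled with their principal-composition
#' counterparts (lifted back to taxon space, see [lift_scores()]). Each
#' sample is a pair of points; the radius of the smallest circle covering a
#' pair measures the distortion introduced by the amalgamation.
#'
#' @param X Original composition matrix.
#' @param R `amalgamation_matrix` of the cut (e.g. `cut(path, k)$R`).
#' @param seed Integer seed for the NMDS starts.
#' @param trymax Random starts for [vegan::metaMDS()].
#' @return A `paa_ordination` object: 2n-by-2 `points`, the `pairing`
#'   index matrix, `stress`, `converged`, `k` and `seed`.
#' @export
ordinate <- function(X, R, seed = 42L, trymax = 16L) {
  stopifnot(inherits(R, "amalgamation_matrix"))
  n <- nrow(X)
  lifted <- lift_scores(X, R)
  stacked <- rbind(unclass(X), unclass(lifted))
  # bitwise-identical rows are indistinguishable at zero dissimilarity; fit
  # the embedding on the distinct rows and replicate coordinates, so an
  # identity amalgamation yields exactly coincident pairs
  key <- apply(stacked, 1, paste, collapse = "\r")
  rep_idx <- match(key, key)
  uniq <- which(rep_idx == seq_along(key))
  if (length(uniq) < 3L)
    stop("fewer than 3 distinct samples; ordination is not meaningful")
  D <- vegan::vegdist(stacked[uniq, , drop = FALSE], method = "bray")
  set.seed(seed)
  fit <- suppressWarnings(vegan::metaMDS(D, k = 2, trymax = trymax, trace = 0))
  if (!isTRUE(fit$converged == 1) && !isTRUE(fit$converged)) {
    fit2 <- suppressWarnings(vegan::metaMDS(D, k = 2, trymax = 2 * trymax,
                                            trace = 0, previous.best = fit))
    fit <- fit2
  }
  pts <- fit$points[match(rep_idx, uniq), , drop = FALSE]
  rownames(pts) <- c(paste0(rownames(X), ".orig"), paste0(rownames(X), ".pc"))
  structure(list(points = pts, pairing = cbind(original = seq_len(n),
                                               amalgamated = n + seq_len(n)),
                 stress = fit$stress,
                 converged = isTRUE(fit$converged == 1) || isTRUE(fit$converged),
                 k = R$k, seed = seed), class = "paa_ordination")
}

#' @export
print.paa_ordination <- function(x, ...) {
  cat("NMDS ordination: ", nrow(x$pairing), " sample pairs, k = ", x$k,
      ", stress = ", format(x$stress, digits = 4),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Ordination plot with distortion circles
#'
#' Plots the paired NMDS coordinates from [ordinate()]: original samples and
#' principal compositions, each pair enclosed by its smallest covering circle
#' (center at the midpoint, radius half the pair distance).
#'
#' @param result A `paa_ordination`.
#' @return A ggplot object.
#' @export
plot_ordination <- function(result) {
  stopifnot(inherits(result, "paa_ordination"))
  pts <- result$points
  n <- nrow(result$pairing)
  dat <- data.frame(x = pts[, 1], y = pts[, 2],
                    set = rep(c("original", "principal compositions"), each = n))
  a <- pts[result$pairing[, 1], , drop = FALSE]
  b <- pts[result$pairing[, 2], , drop = FALSE]
  cx <- (a[, 1] + b[, 1]) / 2; cy <- (a[, 2] + b[, 2]) / 2
  r <- sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2) / 2
  theta <- seq(0, 2 * pi, length.out = 64L)
  circles <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(id = i, x = cx[i] + r[i] * cos(theta),
               y = cy[i] + r[i] * sin(theta))))
  ggplot2::ggplot() +
    ggplot2::geom_path(ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
                       data = circles, colour = "grey60", linewidth = 0.25) +
    ggplot2::geom_point(ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$set, shape = .data$set),
                        data = dat, size = 1.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "NMDS1", y = "NMDS2",
                  subtitle = paste0("k = ", result$k, ", stress = ",
                                    format(result$stress, digits = 3)),
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Pair distortion radii of an ordination
#'
#' @param result A `paa_ordination`.
#' @return Numeric vector of the per-sample circle radii.
#' @export
ordination_radii <- function(result) {
  a <- result$points[result$pairing[, 1], , drop = FALSE]
  b <- result$points[result$pairing[, 2], , drop = FALSE]
  sqrt(rowSums((a - b)^2)) / 2
}
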