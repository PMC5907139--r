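#' Clipped Pearson correlation matrix of expression time courses
#'
#' Takes logs (base 10 by default) of the fold-change series, computes
#' pairwise Pearson correlations, and clips negative values to zero so that
#' downstream clusters contain only positively correlated time courses.
#' Constant (zero-variance) series get correlation 0 with a warning.
#'
#' @param series Long expression series data frame (\code{gene, time_h,
#'   fold_change}); every gene must cover the same time points with
#'   positive values.
#' @param log_base Base of the log transform (default 10).
#' @return A \code{correlation_matrix}: list with \code{genes} and
#'   \code{r_clipped} (symmetric matrix, unit diagonal, entries in [0,1]).
#' @export
correlation_matrix <- function(series, log_base = 10) {
  wide <- series_to_matrix(series)
  if (any(wide <= 0))
    stop("fold changes must be positive for the log transform", call. = FALSE)
  lw <- log(wide, base = log_base)
  const <- apply(lw, 1L, function(r) stats::sd(r) < .Machine$double.eps^0.5)
  r <- suppressWarnings(stats::cor(t(lw), method = "pearson"))
  r <- (r + t(r)) / 2    # enforce exact symmetry
  if (any(const)) {
    warning(sprintf("constant series (correlation set to 0): %s",
                    paste(rownames(lw)[const], collapse = ", ")),
            call. = FALSE)
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[r < 0] <- 0
  diag(r) <- 1
  structure(list(genes = rownames(lw), r_clipped = r),
            class = "correlation_matrix")
}

# gene x time matrix from the long series table
series_to_matrix <- function(series) {
  genes <- unique(series$gene)
  times <- sort(unique(series$time_h))
  m <- matrix(NA_real_, length(genes), length(times),
              dimnames = list(genes, as.character(times)))
  for (g in genes) {
    sub <- series[series$gene == g, ]
    idx <- match(times, sub$time_h)
    if (anyNA(idx))
      stop(sprintf("gene '%s' does not cover all time points", g),
           call. = FALSE)
    m[g, ] <- sub$fold_change[idx]
  }
  m
}

#' Hierarchically cluster genes on their correlation profiles
#'
#' Each gene's feature vector is its row of the clipped correlation matrix;
#' genes are agglomerated with average linkage on euclidean distances and
#' the tree is cut at \code{cut_height}. Genes left as singletons at the
#' cut are reported \code{"UNCLUSTERED"}.
#'
#' @param cmat A \code{correlation_matrix}.
#' @param cut_height Height at which the average-linkage tree is cut.
#' @return A \code{cluster_assignment}: list with \code{assignment} (named
#'   character vector, cluster id \code{"1"}, \code{"2"}, ... in order of
#'   first gene appearance, or \code{"UNCLUSTERED"}), \code{hclust} (the
#'   merge tree) and \code{cut_height}.
#' @export
cluster_genes <- function(cmat, cut_height) {
  if (!inherits(cmat, "correlation_matrix"))
    stop("cmat must be a correlation_matrix", call. = FALSE)
  r <- cmat$r_clipped
  if (nrow(r) < 2L) stop("need at least two genes to cluster", call. = FALSE)
  d <- stats::dist(r, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  assignment <- stats::setNames(rep("UNCLUSTERED", length(raw)), names(raw))
  next_id <- 1L
  for (g in names(raw)) {               # label clusters by first appearance
    cl <- raw[[g]]
    if (sizes[[as.character(cl)]] < 2L) next
    if (assignment[[g]] == "UNCLUSTERED") {
      members <- names(raw)[raw == cl]
      assignment[members] <- as.character(next_id)
      next_id <- next_id + 1L
    }
  }
  structure(list(assignment = assignment, hclust = hc,
                 cut_height = cut_height),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  ids <- setdiff(unique(x$assignment), "UNCLUSTERED")
  cat(sprintf("%d clusters (cut height %.3g), %d unclustered gene(s)\n",
              length(ids), x$cut_height,
              sum(x$assignment == "UNCLUSTERED")))
  for (id in ids)
    cat(sprintf("  cluster %s: %s\n", id,
                paste(names(x$assignment)[x$assignment == id],
                      collapse = ", ")))
  un <- names(x$assignment)[x$assignment == "UNCLUSTERED"]
  if (length(un)) cat("  unclustered:", paste(un, collapse = ", "), "\n")
  invisible(x)
}

#' Direction-symbol pattern of a fold-change time course
#'
#' Signs of consecutive log10 fold-change differences, with a dead band:
#' \code{|diff| < epsilon} reads \code{"0"}.
#'
#' @param fold_change Positive fold-change values in time order.
#' @param epsilon Dead band on the log10 scale (default 0.05, suppressing
#'   replicate-level wobble).
#' @return String over \code{+ - 0}, one symbol per interval.
#' @export
pattern_symbols <- function(fold_change, epsilon = 0.05) {
  if (any(fold_change <= 0)) stop("fold changes must be positive",
                                  call. = FALSE)
  d <- diff(log10(fold_change))
  s <- ifelse(abs(d) < epsilon, "0", ifelse(d > 0, "+", "-"))
  paste(s, collapse = "")
}

#' Per-cluster qualitative pattern descriptors
#'
#' For each cluster, averages the member genes' log10 fold changes at each
#' time point and encodes the mean trajectory as a direction-symbol string
#' (see [pattern_symbols()]); unclustered genes get their own per-gene
#' descriptor keyed by gene name.
#'
#' @param series Long expression series data frame.
#' @param assignment A \code{cluster_assignment} or a named gene ->
#'   cluster-id character vector.
#' @param epsilon Dead band on the log10 scale.
#' @return Named character vector of symbol strings: one entry per cluster
#'   id and one per unclustered gene.
#' @export
assign_patterns <- function(series, assignment, epsilon = 0.05) {
  if (inherits(assignment, "cluster_assignment"))
    assignment <- assignment$assignment
  wide <- series_to_matrix(series)
  lw <- log10(wide)
  out <- character(0)
  ids <- setdiff(unique(assignment), "UNCLUSTERED")
  for (id in ids) {
    members <- intersect(names(assignment)[assignment == id], rownames(lw))
    if (length(members) == 0L) next
    mean_l <- colMeans(lw[members, , drop = FALSE])
    out[id] <- pattern_symbols(10^mean_l, epsilon)
  }
  un <- intersect(names(assignment)[assignment == "UNCLUSTERED"],
                  rownames(lw))
  for (g in un) out[g] <- pattern_symbols(wide[g, ], epsilon)
  out
}

#' Write a correlation matrix / cluster assignment to TSV
#'
#' @param cmat A \code{correlation_matrix}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_correlation_tsv <- function(cmat, path) {
  utils::write.table(cmat$r_clipped, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_correlation_tsv
#' @param clusters A \code{cluster_assignment}.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- data.frame(gene = names(clusters$assignment),
                   cluster = unname(clusters$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a clustered correlation heatmap
#'
#' Orders genes by the average-linkage tree and rasters the clipped
#' correlation matrix (white = 0 to dark blue = 1). Skipped silently where
#' no PNG device is available.
#'
#' @param cmat A \code{correlation_matrix}.
#' @param clusters A \code{cluster_assignment} on the same genes.
#' @param path PNG output path.
#' @return The path (or \code{NULL} if no PNG device), invisibly.
#' @export
plot_clustermap <- function(cmat, clusters, path) {
  if (!isTRUE(capabilities("png"))) return(invisible(NULL))
  ord <- clusters$hclust$order
  m <- cmat$r_clipped[ord, ord]
  grDevices::png(path, width = 160 + 22 * ncol(m),
                 height = 160 + 22 * nrow(m), res = 96)
  op <- graphics::par(mar = c(7, 7, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  pal <- grDevices::colorRampPalette(c("white", "steelblue4"))(64)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(0, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  invisible(path)
}
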