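#' Hierarchical clustering of sorption profiles
#'
#' Clusters either the sorbents (columns) or the compounds (rows) of a
#' K_bc matrix by the similarity of their sorption profiles.
#' K_bc values span more than an order of magnitude across
#' compound-sorbent combinations, so by default they are
#' log10-transformed and then z-scored per feature before Euclidean
#' distances and average-linkage agglomeration. Censored
#' (complete-removal) cells carry no finite coefficient; by default
#' every sorbent column containing one is dropped with a notice, or
#' they can be imputed at their censoring lower bound.
#'
#' @param kbc a `kbc_matrix` (see [build_kbc_matrix()]) or a plain
#'   numeric compounds-by-sorbents matrix with dimnames.
#' @param axis `"sorbents"` to cluster columns, `"compounds"` for rows.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param metric distance metric passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @param log_transform,standardize preprocessing switches (both
#'   default `TRUE`).
#' @param censored `"drop"` (default) removes sorbents with censored
#'   cells; `"impute"` substitutes the censoring lower bound.
#' @return a `sorption_dendrogram`, which is an [stats::hclust()] tree
#'   with the leaf labels of the chosen axis and an attached
#'   `preprocessing` descriptor (transform, standardization, metric,
#'   linkage, dropped items).
#' @export
cluster_profiles <- function(kbc, axis = c("sorbents", "compounds"),
                             linkage = "average", metric = "euclidean",
                             log_transform = TRUE, standardize = TRUE,
                             censored = c("drop", "impute")) {
  axis <- match.arg(axis)
  censored <- match.arg(censored)
  if (inherits(kbc, "kbc_matrix")) {
    values <- kbc$values
    cens <- kbc$censored
  } else {
    values <- as.matrix(kbc)
    cens <- matrix(FALSE, nrow(values), ncol(values))
  }
  dropped <- character(0)
  if (any(cens)) {
    if (censored == "drop") {
      bad <- colSums(cens) > 0
      dropped <- colnames(values)[bad]
      message("dropping sorbent(s) with censored (complete-removal) cells: ",
              paste(dropped, collapse = ", "))
      values <- values[, !bad, drop = FALSE]
    }
    # impute: censored cells already hold the lower bound; use as-is
  }
  m <- if (axis == "sorbents") t(values) else values
  if (nrow(m) < 2L)
    stop("need at least 2 items on the '", axis, "' axis to cluster",
         call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0 & log_transform))
    stop("K_bc matrix must be finite (and positive for the log transform)",
         call. = FALSE)
  if (log_transform) m <- log10(m)
  if (standardize) {
    sds <- apply(m, 2L, stats::sd)
    m <- scale(m, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  d <- stats::dist(m, method = metric)
  if (all(d == 0))
    warning("all pairwise distances are zero (constant matrix); ",
            "the tree merges everything at height 0")
  hc <- stats::hclust(d, method = linkage)
  hc$call <- NULL
  attr(hc, "preprocessing") <- list(
    axis = axis, log_transform = log_transform, standardize = standardize,
    metric = metric, linkage = linkage, dropped = dropped)
  class(hc) <- c("sorption_dendrogram", "hclust")
  hc
}

#' Cut a sorption dendrogram into k flat clusters
#'
#' @param dendrogram a `sorption_dendrogram` (or any `hclust` tree).
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return named integer vector of cluster labels, one per leaf.
#' @export
cut_tree <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (k < 1 || k > n)
    stop("k must lie between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  stats::cutree(stats::as.hclust(dendrogram), k = k)
}

#' Serialize a dendrogram
#'
#' `dendrogram_newick()` writes the tree as a Newick string with branch
#' lengths equal to merge-height differences; `merge_table()` returns
#' the merge sequence as a data frame (one row per agglomeration:
#' the two merged nodes, the merge height and the resulting size),
#' convenient for JSON export.
#'
#' @param dendrogram a `sorption_dendrogram`.
#' @return a Newick string, or a data frame.
#' @export
dendrogram_newick <- function(dendrogram) {
  phy <- ape::as.phylo(stats::as.hclust(dendrogram))
  ape::write.tree(phy)
}

#' @rdname dendrogram_newick
#' @export
merge_table <- function(dendrogram) {
  hc <- stats::as.hclust(dendrogram)
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(j) if (j < 0) 1L else sizes[j]
    sizes[i] <- sz(hc$merge[i, 1L]) + sz(hc$merge[i, 2L])
  }
  data.frame(node_a = hc$merge[, 1L], node_b = hc$merge[, 2L],
             height = hc$height, size = sizes)
}
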