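#' Hierarchically cluster cell-line samples over a drug signature
#'
#' Restricts the data to the signature's features (signature members absent
#' from the measured features — e.g. transcripts in a protein-only dataset —
#' are dropped with a warning and the count logged), z-scores each feature
#' row, and clusters samples by average-linkage agglomerative clustering on
#' Euclidean distance. Columns are ordered by sample id before clustering so
#' the result does not depend on input order.
#'
#' @param data a `cell_line_dataset` (or any list with a feature x sample
#'   `values` matrix).
#' @param signature a `drug_signature`, or a character vector of feature
#'   ids.
#' @param k number of clusters to cut the tree into (default 2).
#' @return list with `tree` (an `hclust`), `labels` (named cluster
#'   assignment from `cutree`), `n_features` used and `n_dropped`.
#' @export
cluster_signature <- function(data, signature, k = 2L) {
  vals <- if (is.list(data)) data$values else data
  feats <- if (inherits(signature, "drug_signature"))
    signature$features$feature else as.character(signature)
  feats <- unique(feats)
  present <- intersect(feats, rownames(vals))
  dropped <- length(feats) - length(present)
  if (dropped > 0L)
    warning(sprintf("%d signature feature(s) not measured; using %d",
                    dropped, length(present)))
  if (length(present) < 2L)
    stop("fewer than 2 usable signature features", call. = FALSE)
  m <- vals[present, order(colnames(vals)), drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  m <- (m - rowMeans(m)) / ifelse(sds > 0, sds, 1)
  d <- stats::dist(t(m), method = "euclidean")
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  list(tree = tree, labels = labels, n_features = length(present),
       n_dropped = dropped)
}

#' Adjusted Rand index between cluster and group labels
#'
#' Chance-corrected partition agreement: 1 for identical partitions,
#' expectation 0 under random labeling. The degenerate case of two
#' single-block partitions (where the correction is 0/0) is defined as 1,
#' since the partitions are identical.
#'
#' @param cluster_labels,group_labels equal-length label vectors.
#' @return the ARI, a single number.
#' @export
separation_score <- function(cluster_labels, group_labels) {
  stopifnot(length(cluster_labels) == length(group_labels))
  if (length(unique(cluster_labels)) == 1L &&
      length(unique(group_labels)) == 1L) return(1)
  mclust::adjustedRandIndex(as.character(cluster_labels),
                            as.character(group_labels))
}

#' Order resistance stages by cophenetic proximity to parental cells
#'
#' Clusters the samples over the signature and compares the mean cophenetic
#' distance between parental-early sample pairs with that of parental-late
#' pairs. In the two-step resistance model, early-resistant cultures should
#' sit closer to parental cells than late-resistant ones.
#'
#' @inheritParams cluster_signature
#' @param groups named factor/character vector assigning each sample to
#'   `parental`, `early`, or `late` (defaults to `data$groups`).
#' @return list with `d_parental_early`, `d_parental_late`,
#'   `early_closer` (logical), and the `tree`.
#' @export
resistance_stage_proximity <- function(data, signature, groups = NULL) {
  groups <- groups %||% data$groups
  groups <- stats::setNames(as.character(groups), names(groups))
  for (g in c("parental", "early", "late"))
    if (!any(groups == g))
      stop(sprintf("group '%s' is missing from the dataset", g), call. = FALSE)
  cl <- cluster_signature(data, signature, k = 2L)
  coph <- as.matrix(stats::cophenetic(cl$tree))
  ids <- rownames(coph)
  pe <- mean(coph[ids[groups[ids] == "parental"],
                  ids[groups[ids] == "early"], drop = FALSE])
  pl <- mean(coph[ids[groups[ids] == "parental"],
                  ids[groups[ids] == "late"], drop = FALSE])
  list(d_parental_early = pe, d_parental_late = pl,
       early_closer = pe < pl, tree = cl$tree)
}
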