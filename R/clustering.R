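# Complete-linkage hierarchical clustering of per-gene log2FC profiles
# with threshold-based semiautomated cluster extraction.

#' Expression matrix for clustering
#'
#' Rows are genes significant in at least one contrast, columns the
#' contrasts, values the log2 fold changes; untested / undefined log2FC
#' becomes 0 (absent contrasts carry no signal).
#'
#' @param de_results named list of [de_test()] data.frames.
#' @return numeric matrix (genes x contrasts).
#' @export
expression_matrix <- function(de_results) {
  sig <- unique(unlist(lapply(de_results, function(d) {
    d$gene_id[d$significant]
  })))
  if (!length(sig)) stop("no significant genes in any contrast")
  m <- vapply(de_results, function(d) {
    v <- d$log2fc[match(sig, d$gene_id)]
    ifelse(is.na(v), 0, v)
  }, numeric(length(sig)))
  m <- matrix(m, nrow = length(sig),
              dimnames = list(sig, names(de_results)))
  m
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with Euclidean distances and
#' complete linkage (inter-cluster distance = maximum pairwise
#' distance), as computed by [stats::hclust()].
#'
#' @param matrix numeric matrix with at least 2 rows.
#' @return An [stats::hclust] object (merge heights non-decreasing,
#'   n - 1 merges for n leaves).
#' @export
complete_linkage <- function(matrix) {
  if (nrow(matrix) < 2) stop("need at least 2 rows to cluster")
  stats::hclust(stats::dist(matrix, method = "euclidean"),
                method = "complete")
}

#' Extract clusters from a dendrogram
#'
#' Cuts the tree into `top_k` clusters; the largest resulting cluster is
#' optionally re-cut at height `sub_threshold` into subclusters
#' (labelled `<cluster>.<i>`).
#'
#' @param dendrogram an [stats::hclust] object.
#' @param top_k number of top-level clusters (default 2).
#' @param sub_threshold height for subdividing the largest cluster, or
#'   NULL for no subdivision (default 7).
#' @return named character vector of cluster labels, one per leaf.
#' @export
cut_clusters <- function(dendrogram, top_k = 2, sub_threshold = 7) {
  n <- length(dendrogram$order)
  if (top_k > n) stop("top_k exceeds number of leaves")
  top <- stats::cutree(dendrogram, k = top_k)
  labels <- paste0("C", top)
  names(labels) <- names(top)
  if (!is.null(sub_threshold) && top_k < n) {
    sizes <- table(top)
    big <- as.integer(names(sizes)[which.max(sizes)])
    root_h <- max(dendrogram$height)
    if (sub_threshold < root_h) {
      sub <- stats::cutree(dendrogram, h = sub_threshold)
      inbig <- top == big
      subs <- sub[inbig]
      relab <- match(subs, unique(subs))
      if (length(unique(relab)) > 1) {
        labels[inbig] <- paste0("C", big, ".", relab)
      }
    }
  }
  labels
}

#' Export a clustered matrix in dendrogram leaf order
#'
#' @param matrix the clustered matrix.
#' @param dendrogram its [complete_linkage()] tree.
#' @param labels cluster labels from [cut_clusters()].
#' @param path output TSV path.
#' @return The exported data.frame, invisibly.
#' @export
heatmap_export <- function(matrix, dendrogram, labels, path) {
  ord <- dendrogram$order
  out <- data.frame(gene_id = rownames(matrix)[ord],
                    cluster = unname(labels[rownames(matrix)[ord]]),
                    matrix[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Mean profile per cluster
#'
#' @param matrix expression matrix.
#' @param labels cluster labels.
#' @return data.frame: `cluster, n, mean` (grand mean of the profile).
#' @export
cluster_profiles <- function(matrix, labels) {
  labs <- labels[rownames(matrix)]
  agg <- tapply(rowMeans(matrix), labs, mean)
  data.frame(cluster = names(agg), n = as.integer(table(labs)[names(agg)]),
             mean = as.numeric(agg), stringsAsFactors = FALSE)
}
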