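# Agglomerative single-linkage clustering of descriptor tables on Euclidean
# distances, with dendrogram export (Newick, merge table).

#' Single-linkage hierarchical clustering of a descriptor table
#'
#' Euclidean distances, single linkage (the distance between two clusters is
#' the distance of their two closest members). By default columns are z-scored
#' first, dropping zero-variance columns with a message: raw Euclidean
#' distance is dominated by formula weight, and only standardized distances
#' expose the PSA / H-bond-count deviations that isolate the hydroxylated
#' agent in the reference set.
#'
#' @param t A `descriptor_table` (or data frame with numeric columns); at
#'   least 2 records.
#' @param standardize Z-score columns before computing distances.
#' @return A `cluster_tree`: list with `merges` (per merge: the two member
#'   sets and the Euclidean merge height), `labels`, `standardize`,
#'   `dropped_columns` and the underlying [stats::hclust] object.
#' @examples
#' ct <- cluster_tree(builtin_table1())
#' last_merged_singleton(ct)  # "12"
#' @export
cluster_tree <- function(t, standardize = TRUE) {
  df <- as.data.frame(t)
  if (nrow(df) < 2L) stop_input("cluster_tree: need at least 2 records")
  labels <- df$agent_id %||% as.character(seq_len(nrow(df)))
  m <- as.matrix(df[numeric_fields(df)])
  dropped <- character(0)
  if (standardize) {
    sc <- scale_drop_constant(m)
    m <- sc$scaled
    dropped <- sc$dropped
  }
  rownames(m) <- labels
  h <- stats::hclust(stats::dist(m), method = "single")
  members <- lapply(seq_len(nrow(df)), function(i) labels[i])
  merges <- vector("list", nrow(h$merge))
  clusters <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    pick <- function(j) if (j < 0) members[[-j]] else clusters[[j]]
    a <- pick(h$merge[k, 1]); b <- pick(h$merge[k, 2])
    clusters[[k]] <- c(a, b)
    merges[[k]] <- list(a = a, b = b, height = h$height[k])
  }
  structure(list(merges = merges, labels = labels, hclust = h,
                 standardize = standardize, dropped_columns = dropped),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> ", length(x$labels), " leaves, ",
      length(x$merges), " merges (single linkage",
      if (x$standardize) ", standardized", ")\n", sep = "")
  mt <- merge_table(x)
  print(utils::tail(mt, 5))
  invisible(x)
}

#' Merge table of a cluster tree
#'
#' @param ct A [cluster_tree()].
#' @return Data frame `cluster_a`, `cluster_b`, `height`, one row per merge in
#'   order of increasing height; members joined with `"|"`.
#' @export
merge_table <- function(ct) {
  stopifnot(inherits(ct, "cluster_tree"))
  do.call(rbind, lapply(ct$merges, function(m) {
    data.frame(cluster_a = paste(m$a, collapse = "|"),
               cluster_b = paste(m$b, collapse = "|"),
               height = m$height, stringsAsFactors = FALSE)
  }))
}

#' Newick serialization of a cluster tree
#'
#' @param ct A [cluster_tree()].
#' @return A Newick string (with branch lengths from merge heights).
#' @export
as_newick <- function(ct) {
  stopifnot(inherits(ct, "cluster_tree"))
  phy <- ape::as.phylo(ct$hclust)
  ape::write.tree(phy)
}

#' Label of the last cluster to join the tree, if it is a singleton
#'
#' In the reference agent set the hydroxylated agent "12" is the final
#' singleton to merge: the most distant leaf of the dendrogram.
#'
#' @param ct A [cluster_tree()].
#' @return The label, or `NA_character_` if the final merge joins two
#'   multi-member clusters.
#' @export
last_merged_singleton <- function(ct) {
  stopifnot(inherits(ct, "cluster_tree"))
  last <- ct$merges[[length(ct$merges)]]
  if (length(last$a) == 1L) return(last$a)
  if (length(last$b) == 1L) return(last$b)
  NA_character_
}
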