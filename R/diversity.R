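#' Shannon entropy of taxon counts (bits)
#'
#' `H = -sum(p_i * log2(p_i))` with `p_i` the relative abundance of each
#' taxon among the windows of one family; zero-count taxa contribute 0.
#' Bounded by `0 <= H <= log2(n_taxa)`.
#'
#' @param counts non-negative numeric vector (optionally named by taxon).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop("negative taxon counts")
  total <- sum(counts)
  if (total <= 0) stop("all-zero taxon counts")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Categorize entropy values by the interquartile range
#'
#' Quartiles are computed by linear interpolation. Values up to Q3
#' (including everything below Q1) are `low`; values in the right whisker
#' (Q3, Q3 + 1.5 IQR] are `medium`; values beyond the whisker are `high`.
#' With fewer than 4 values the spread is not estimable and everything is
#' labelled low with a warning.
#'
#' @param values numeric vector of entropies.
#' @return character vector of categories, same length/names as `values`.
#' @export
categorize_entropy <- function(values) {
  out <- rep("low", length(values))
  names(out) <- names(values)
  if (length(values) < 4) {
    warning("fewer than 4 entropy values; all categorized as low",
            call. = FALSE)
    return(out)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  whisker <- q[2] + 1.5 * iqr
  out[values > q[2]] <- "medium"
  out[values > whisker] <- "high"
  out
}

#' Taxonomic diversity report for window families
#'
#' Counts windows per taxon at the chosen rank within each family, computes
#' Shannon entropy, and categorizes the entropies by IQR across families.
#'
#' @param taxa data.frame with `window_id`, `family_id` and one column per
#'   rank (e.g. `phylum` ... `species`).
#' @param rank column name to use.
#' @return data.frame `family_id`, `H`, `n_taxa`, `n_windows`, `category`.
#' @export
entropy_report <- function(taxa, rank) {
  stopifnot(rank %in% names(taxa), "family_id" %in% names(taxa))
  fams <- split(taxa[[rank]], taxa$family_id)
  H <- vapply(fams, function(x) shannon_entropy(table(x)), 0)
  df <- data.frame(family_id = names(fams), H = unname(H),
                   n_taxa = vapply(fams, function(x) length(unique(x)), 0L),
                   n_windows = vapply(fams, length, 0L),
                   stringsAsFactors = FALSE)
  df$category <- suppressWarnings(unname(categorize_entropy(df$H)))
  df
}

#' Hierarchically cluster a GFS matrix for heatmap ordering
#'
#' Row vectors -> pairwise Euclidean distances -> agglomerative clustering
#' with complete linkage -> dendrogram leaf order for the heatmap rows and
#' columns.
#'
#' @param matrix numeric GFS matrix with row names.
#' @return list of class `gator_cluster`: `order` (window ids in leaf
#'   order), `hclust` (the merge tree; `NULL` for a single row).
#' @export
cluster_gfs <- function(matrix) {
  m <- unclass(matrix)
  if (any(!is.finite(m))) stop("GFS matrix contains non-finite cells")
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (nrow(m) < 2)
    return(structure(list(order = rownames(m), hclust = NULL),
                     class = "gator_cluster"))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  structure(list(order = hc$labels[hc$order], hclust = hc),
            class = "gator_cluster")
}

#' Export network edge/node tables for a window set
#'
#' Plumbing for external network tools: one edge per ordered window pair
#' with its GFS, plus a node table with window metadata.
#'
#' @param gfs_matrix all-vs-all score matrix.
#' @param windows the scored windows.
#' @param out_dir directory for `network_edges.csv` / `network_nodes.csv`.
#' @param min_gfs drop edges below this score.
#' @return invisible list of the two data.frames.
#' @export
export_network_tables <- function(gfs_matrix, windows, out_dir,
                                  min_gfs = 0) {
  ids <- rownames(gfs_matrix)
  edges <- do.call(rbind, lapply(seq_along(ids), function(j) {
    data.frame(source = ids[j], target = ids, gfs = gfs_matrix[, j],
               stringsAsFactors = FALSE)
  }))
  edges <- edges[edges$source != edges$target & edges$gfs >= min_gfs, ]
  nodes <- data.frame(
    window_id = vapply(windows, `[[`, "", "window_id"),
    genome_id = vapply(windows, `[[`, "", "genome_id"),
    contig_id = vapply(windows, `[[`, "", "contig_id"),
    length_bp = vapply(windows, window_length, 0),
    n_genes = vapply(windows, function(w) nrow(w$genes), 0L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(edges, file.path(out_dir, "network_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(nodes, file.path(out_dir, "network_nodes.csv"),
                   row.names = FALSE)
  invisible(list(edges = edges, nodes = nodes))
}
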