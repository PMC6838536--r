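# Gate-purity arm: cell filtering, clustering (pluggable contract),
# marker-panel identity assignment, confusion/purity reporting, and
# per-cluster enriched genes.

#' Filter cells by total transcript count
#'
#' Retains exactly the cells whose total count is strictly greater than
#' `min_transcripts` (a cell at exactly the threshold is removed).
#'
#' @param matrix A [single_cell_matrix()].
#' @param min_transcripts Minimum total transcripts; default 1500.
#' @return The filtered [single_cell_matrix()].
#' @export
filter_cells <- function(matrix, min_transcripts = 1500) {
  stopifnot(inherits(matrix, "sc_matrix"), min_transcripts >= 0)
  totals <- colSums(matrix$counts)
  keep <- totals > min_transcripts
  message(sprintf("retained %d of %d cells (> %s transcripts)",
                  sum(keep), length(keep), format(min_transcripts)))
  if (!any(keep)) {
    warning("all cells removed by the transcript filter")
    return(structure(list(counts = matrix$counts[, 0, drop = FALSE],
                          gene_ids = matrix$gene_ids, cell_ids = character(),
                          gate_labels = matrix$gate_labels[0]),
                     class = "sc_matrix"))
  }
  single_cell_matrix(matrix$counts[, keep, drop = FALSE],
                     matrix$gate_labels[keep])
}

#' Unique genes detected per cell
#'
#' A cell's value is the number of genes with a nonzero count; the summary
#' is the mean with its standard error over cells.
#'
#' @param matrix A [single_cell_matrix()].
#' @return List with `per_cell` (named integer vector), `mean` and `sem`.
#' @export
genes_per_cell <- function(matrix) {
  stopifnot(inherits(matrix, "sc_matrix"))
  per_cell <- colSums(matrix$counts > 0)
  n <- length(per_cell)
  list(per_cell = per_cell,
       mean = if (n > 0) mean(per_cell) else NA_real_,
       sem = if (n > 1) stats::sd(per_cell) / sqrt(n) else NA_real_)
}

# Depth-normalise to the median cell total, then log transform.
normalise_counts <- function(counts) {
  totals <- colSums(counts)
  totals[totals == 0] <- 1
  target <- stats::median(colSums(counts))
  if (target == 0) target <- 1
  log1p(sweep(counts, 2, target / totals, "*"))
}

#' Cluster cells on depth-normalised log counts
#'
#' The clustering stage is a pluggable contract: any function mapping a
#' cells x features matrix and k to an integer assignment can stand behind
#' it. The default is k-means over the most variable genes after per-cell
#' depth normalisation (scaling every cell to the median total count) and a
#' log1p transform. Deterministic under a fixed seed.
#'
#' @param matrix A filtered [single_cell_matrix()].
#' @param k Number of clusters, or `"auto"` to choose k in 2..`k_max` by
#'   maximising the mean silhouette width.
#' @param seed Integer seed for the clusterer.
#' @param n_var_genes Number of top-variance genes used; default 100.
#' @param k_max Largest k considered when `k = "auto"`.
#' @param method A clustering function `function(x, k)` returning an integer
#'   vector of length `nrow(x)`; defaults to k-means (20 restarts).
#' @return List of class `"cluster_assignment"`: `clusters` (named integer
#'   vector over cells) and `n_clusters`.
#' @export
cluster_cells <- function(matrix, k = "auto", seed = 1, n_var_genes = 100,
                          k_max = 8, method = NULL) {
  stopifnot(inherits(matrix, "sc_matrix"))
  n_cells <- ncol(matrix$counts)
  if (n_cells == 0) stop("no cells to cluster")
  if (is.numeric(k) && k > n_cells) {
    stop(sprintf("k = %d exceeds the %d available cells", k, n_cells))
  }
  norm <- normalise_counts(matrix$counts)
  vars <- apply(norm, 1, stats::var)
  top <- utils::head(order(vars, decreasing = TRUE),
                     min(n_var_genes, nrow(norm)))
  x <- t(norm[top, , drop = FALSE])
  if (is.null(method)) {
    method <- function(x, k) {
      if (k == 1) return(rep(1L, nrow(x)))
      stats::kmeans(x, centers = k, nstart = 20, iter.max = 100)$cluster
    }
  }
  clusters <- with_seed(seed, {
    if (identical(k, "auto")) {
      ks <- 2:min(k_max, n_cells - 1)
      d <- stats::dist(x)
      sil <- vapply(ks, function(kk) {
        cl <- method(x, kk)
        if (length(unique(cl)) < 2) return(-1)
        mean(cluster::silhouette(cl, d)[, "sil_width"])
      }, numeric(1))
      method(x, ks[which.max(sil)])
    } else {
      method(x, k)
    }
  })
  clusters <- as.integer(clusters)
  names(clusters) <- matrix$cell_ids
  structure(list(clusters = clusters, n_clusters = length(unique(clusters))),
            class = "cluster_assignment")
}

#' Assign a cell-type identity to each cluster from marker panels
#'
#' Each cluster receives the type whose marker panel shows the highest mean
#' normalised expression in that cluster, mirroring marker-based cluster
#' annotation. Ties (including all-zero clusters) are broken towards the
#' lexicographically first type name, with a warning flagging the cluster as
#' low confidence.
#'
#' @param matrix The [single_cell_matrix()] that was clustered.
#' @param assignment A [cluster_cells()] result.
#' @param marker_panels Named list, type -> character vector of marker genes.
#'   Panel genes absent from the matrix are warned about and skipped.
#' @return List with `identity` (named character vector, cluster -> type)
#'   and `scores` (clusters x types mean-panel-expression table for audit).
#' @export
assign_cluster_identity <- function(matrix, assignment, marker_panels) {
  stopifnot(inherits(matrix, "sc_matrix"),
            inherits(assignment, "cluster_assignment"))
  norm <- normalise_counts(matrix$counts)
  types <- sort(names(marker_panels))
  panels <- lapply(marker_panels[types], function(genes) {
    missing <- setdiff(genes, rownames(norm))
    if (length(missing) > 0) {
      warning(sprintf("%d panel genes absent from matrix: %s",
                      length(missing),
                      paste(utils::head(missing, 3), collapse = ", ")))
    }
    intersect(genes, rownames(norm))
  })
  clusters <- sort(unique(assignment$clusters))
  scores <- matrix(0, length(clusters), length(types),
                   dimnames = list(as.character(clusters), types))
  for (ci in seq_along(clusters)) {
    cells <- names(assignment$clusters)[assignment$clusters == clusters[ci]]
    for (t in types) {
      if (length(panels[[t]]) > 0) {
        scores[ci, t] <- mean(norm[panels[[t]], cells, drop = FALSE])
      }
    }
  }
  identity <- apply(scores, 1, function(row) {
    best <- types[row == max(row)]
    if (length(best) > 1) {
      warning(sprintf("tie in panel scores (%s); assigning '%s' (low confidence)",
                      paste(best, collapse = " vs "), best[1]))
    }
    best[1]
  })
  list(identity = identity, scores = scores)
}

#' Gate-versus-identity confusion and purity report
#'
#' Purity of a gate is the percentage of its cells whose cluster-derived
#' identity equals the type the gate was designed to capture. A gate with no
#' cells is reported as `NA`, never as 0 or 100.
#'
#' @param assignment A [cluster_cells()] result.
#' @param identity_map Cluster -> type map from [assign_cluster_identity()]
#'   (the `identity` element), or any named character vector.
#' @param gate_labels Named character vector, cell -> gate.
#' @param expected_type_per_gate Named character vector, gate -> expected
#'   type (e.g. the neural gate is expected to yield neural cells).
#' @return List of class `"purity_report"`: `confusion` (gate x identity
#'   counts), `purity` (named percentages), `n_cells` per gate.
#' @export
compute_purity <- function(assignment, identity_map, gate_labels,
                           expected_type_per_gate) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cells <- names(assignment$clusters)
  missing <- setdiff(cells, names(gate_labels))
  if (length(missing) > 0) stop("cells without gate labels: ", length(missing))
  cell_identity <- unname(identity_map[as.character(assignment$clusters)])
  gates <- names(expected_type_per_gate)
  idents <- sort(unique(c(cell_identity, unname(expected_type_per_gate))))
  confusion <- matrix(0L, length(gates), length(idents),
                      dimnames = list(gate = gates, identity = idents))
  gate_of <- gate_labels[cells]
  for (gi in seq_along(gates)) {
    tab <- table(factor(cell_identity[gate_of == gates[gi]], levels = idents))
    confusion[gi, ] <- as.integer(tab)
  }
  n_cells <- rowSums(confusion)
  purity <- vapply(gates, function(g) {
    if (n_cells[g] == 0) return(NA_real_)
    100 * confusion[g, expected_type_per_gate[g]] / n_cells[g]
  }, numeric(1))
  structure(list(confusion = confusion, purity = purity, n_cells = n_cells),
            class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  cat("Gate purity (% cells matching expected identity):\n")
  for (g in names(x$purity)) {
    cat(sprintf("  %-12s %6s%%  (n = %d)\n", g,
                ifelse(is.na(x$purity[g]), "NA", format(round(x$purity[g], 1))),
                x$n_cells[g]))
  }
  invisible(x)
}

#' Top enriched genes per cluster
#'
#' The enrichment of gene g in cluster c is its mean normalised expression
#' in c divided by the mean over clusters of those cluster means — the same
#' relative-to-mean score used for the bulk populations. Genes with zero
#' mean everywhere are excluded; within a cluster the top `n` genes are
#' ranked by enrichment, ties broken by higher absolute expression in the
#' cluster and then alphabetically.
#'
#' @param matrix A [single_cell_matrix()].
#' @param assignment A [cluster_cells()] result with at least 2 clusters.
#' @param n Genes to report per cluster; default 10.
#' @return Named list (by cluster id) of data frames with columns `gene`,
#'   `enrichment`, `mean_expr`.
#' @export
top_enriched_genes <- function(matrix, assignment, n = 10) {
  stopifnot(inherits(matrix, "sc_matrix"),
            inherits(assignment, "cluster_assignment"))
  if (assignment$n_clusters < 2) stop("need at least 2 clusters")
  norm <- normalise_counts(matrix$counts)
  clusters <- sort(unique(assignment$clusters))
  cmeans <- vapply(clusters, function(cl) {
    rowMeans(norm[, assignment$clusters == cl, drop = FALSE])
  }, numeric(nrow(norm)))
  colnames(cmeans) <- as.character(clusters)
  overall <- rowMeans(cmeans)
  cmeans <- cmeans[overall > 0, , drop = FALSE]
  enr <- cmeans / rowMeans(cmeans)
  if (n > nrow(enr)) {
    warning(sprintf("n = %d exceeds the %d scorable genes; returning all",
                    n, nrow(enr)))
    n <- nrow(enr)
  }
  out <- lapply(as.character(clusters), function(cl) {
    ord <- order(-enr[, cl], -cmeans[, cl], rownames(enr))
    top <- utils::head(ord, n)
    data.frame(gene = rownames(enr)[top], enrichment = enr[top, cl],
               mean_expr = cmeans[top, cl], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  names(out) <- as.character(clusters)
  out
}
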