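#' Filter genes by mean expression across populations
#'
#' Retains genes whose arithmetic mean FPKM across all populations is
#' strictly greater than `min_mean`. A gene sitting exactly at the threshold
#' is removed.
#'
#' @param profile An [expression_profile()].
#' @param min_mean Mean-FPKM cutoff; default 10.
#' @return The filtered [expression_profile()].
#' @export
filter_expressed_genes <- function(profile, min_mean = 10) {
  stopifnot(inherits(profile, "expr_profile"))
  keep <- rowMeans(profile$values) > min_mean
  if (!any(keep)) {
    warning("no genes pass the mean-expression filter")
    return(structure(list(gene_ids = character(), type_ids = profile$type_ids,
                          values = profile$values[0, , drop = FALSE]),
                     class = "expr_profile"))
  }
  expression_profile(profile$values[keep, , drop = FALSE])
}

#' Cross-population enrichment scores
#'
#' For each gene, its expression in each population divided by its mean
#' expression across all populations. A gene expressed in a single one of
#' four populations scores 4 there and 0 elsewhere; the per-gene mean of
#' scores is 1 by construction. Genes with zero expression everywhere are
#' dropped with a warning (their score is undefined).
#'
#' @param profile An [expression_profile()].
#' @return A list of class `"enrichment_matrix"` with `gene_ids`, `type_ids`
#'   and `scores` (genes x populations).
#' @export
enrichment_scores <- function(profile) {
  stopifnot(inherits(profile, "expr_profile"))
  if (length(profile$gene_ids) == 0) stop("empty expression profile")
  means <- rowMeans(profile$values)
  zero <- means == 0
  if (any(zero)) {
    warning(sprintf("dropping %d genes with zero mean expression", sum(zero)))
  }
  vals <- profile$values[!zero, , drop = FALSE]
  scores <- vals / rowMeans(vals)
  structure(list(gene_ids = rownames(scores), type_ids = profile$type_ids,
                 scores = scores),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("Enrichment matrix: %d genes x %d populations (per-gene mean = 1)\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Per-population expression calls
#'
#' Marks gene g as "expressed" in population t when its FPKM there is at
#' least `per_type_min`. With `per_type_min = 0` every entry is called
#' expressed (all FPKM are >= 0); this edge is intentional and documented.
#'
#' @param profile An [expression_profile()], normally already mean-filtered
#'   by [filter_expressed_genes()].
#' @param per_type_min Per-population FPKM threshold; default 10.
#' @return A list of class `"expression_calls"`: logical matrix `calls`
#'   (genes x populations) plus the `threshold` used.
#' @export
call_expression <- function(profile, per_type_min = 10) {
  stopifnot(inherits(profile, "expr_profile"))
  calls <- profile$values >= per_type_min
  structure(list(calls = calls, threshold = per_type_min),
            class = "expression_calls")
}

strength_fun <- function(mode) {
  switch(mode,
         geomean = function(l, r) sqrt(l * r),
         min     = function(l, r) pmin(l, r),
         sum     = function(l, r) l + r,
         product = function(l, r) l * r,
         stop("unknown strength mode: ", mode))
}

#' Build the directed ligand-receptor interaction network
#'
#' An edge (ligand L, receptor R, sender s, receiver r) is created when
#' (L, R) is a catalogued pair, L is called expressed in s and R is called
#' expressed in r. Autocrine edges (s == r) are included; with T populations
#' all T^2 ordered (sender, receiver) combinations are evaluated. Edge
#' strength combines the ligand FPKM in the sender with the receptor FPKM in
#' the receiver (geometric mean by default).
#'
#' Catalogue genes absent from the profile are skipped silently, with a
#' summary count in a message — the expected situation for any
#' catalogue/assay mismatch.
#'
#' @param profile An [expression_profile()], unfiltered; the mean filter is
#'   applied internally.
#' @param lrdb An [lr_database()].
#' @param per_type_min Per-population expression-call threshold (FPKM).
#' @param min_mean Mean-expression filter threshold (FPKM).
#' @param strength One of `"geomean"`, `"min"`, `"sum"`, `"product"`.
#' @param case_insensitive Match catalogue symbols to profile symbols
#'   ignoring case (off by default; symbol casing conventions differ between
#'   species catalogues).
#' @return An object of class `"interaction_network"`: `edges` (data frame
#'   ligand/receptor/sender/receiver/strength, totally ordered), the
#'   `populations`, `pair_counts` (sender x receiver matrix),
#'   `unique_pair_count` (distinct gene pairs with >= 1 edge), `n_edges`, and
#'   `metadata` echoing all thresholds.
#' @export
build_network <- function(profile, lrdb, per_type_min = 10, min_mean = 10,
                          strength = c("geomean", "min", "sum", "product"),
                          case_insensitive = FALSE) {
  stopifnot(inherits(profile, "expr_profile"), inherits(lrdb, "lr_database"))
  strength <- match.arg(strength)
  if (nrow(lrdb$pairs) == 0) stop("empty ligand-receptor database")
  filtered <- filter_expressed_genes(profile, min_mean)
  calls <- call_expression(filtered, per_type_min)
  vals <- filtered$values
  genes <- rownames(vals)
  lookup <- if (case_insensitive) stats::setNames(genes, toupper(genes))
            else stats::setNames(genes, genes)
  key <- function(x) if (case_insensitive) toupper(x) else x
  lig <- unname(lookup[key(lrdb$pairs$ligand)])
  rec <- unname(lookup[key(lrdb$pairs$receptor)])
  present <- !is.na(lig) & !is.na(rec)
  if (any(!present)) {
    message(sprintf("%d of %d catalogue pairs skipped (gene absent from filtered profile)",
                    sum(!present), length(present)))
  }
  types <- filtered$type_ids
  sfun <- strength_fun(strength)
  rows <- vector("list", sum(present))
  n <- 0L
  for (i in which(present)) {
    L <- lig[i]; R <- rec[i]
    senders <- types[calls$calls[L, ]]
    receivers <- types[calls$calls[R, ]]
    if (length(senders) == 0 || length(receivers) == 0) next
    combo <- expand.grid(sender = senders, receiver = receivers,
                         stringsAsFactors = FALSE)
    n <- n + 1L
    rows[[n]] <- data.frame(ligand = L, receptor = R,
                            sender = combo$sender, receiver = combo$receiver,
                            strength = sfun(vals[L, combo$sender],
                                            vals[R, combo$receiver]),
                            stringsAsFactors = FALSE)
  }
  edges <- if (n > 0) do.call(rbind, rows[seq_len(n)])
           else data.frame(ligand = character(), receptor = character(),
                           sender = character(), receiver = character(),
                           strength = numeric())
  interaction_network(edges, types,
                      metadata = list(per_type_min = per_type_min,
                                      min_mean = min_mean,
                                      strength = strength,
                                      case_insensitive = case_insensitive))
}

#' Extract a receptor- or ligand-centric subnetwork
#'
#' Receptor-centric keeps every edge whose receptor is the focus gene (the
#' view used for receptor hubs such as KDR); ligand-centric keeps edges whose
#' ligand is the focus (as for a secreted hub such as APOE). When an
#' enrichment matrix is supplied, the rows of every gene participating in the
#' subnetwork are attached as the heatmap slice.
#'
#' @param network An interaction network.
#' @param focus_gene Gene symbol to centre on.
#' @param mode `"receptor"` or `"ligand"`.
#' @param enrichment Optional [enrichment_scores()] result.
#' @return An interaction network restricted to the focus gene, with an
#'   additional `heatmap` element (enrichment rows) when `enrichment` given.
#' @export
subnetwork <- function(network, focus_gene, mode = c("receptor", "ligand"),
                       enrichment = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  mode <- match.arg(mode)
  all_genes <- unique(c(network$edges$ligand, network$edges$receptor))
  if (!(focus_gene %in% all_genes)) {
    near <- all_genes[tolower(all_genes) == tolower(focus_gene)]
    if (length(near) == 0) {
      d <- utils::adist(focus_gene, all_genes, ignore.case = TRUE)
      near <- all_genes[order(d)][seq_len(min(3, length(all_genes)))]
    }
    stop(sprintf("gene '%s' not in network; near matches: %s",
                 focus_gene, paste(near, collapse = ", ")))
  }
  keep <- if (mode == "receptor") network$edges$receptor == focus_gene
          else network$edges$ligand == focus_gene
  if (!any(keep)) {
    warning(sprintf("'%s' has no edges in %s-centric mode", focus_gene, mode))
  }
  sub <- interaction_network(network$edges[keep, , drop = FALSE],
                             network$populations, metadata = network$metadata)
  if (!is.null(enrichment)) {
    genes <- unique(c(sub$edges$ligand, sub$edges$receptor))
    sub$heatmap <- enrichment$scores[intersect(rownames(enrichment$scores), genes), ,
                                     drop = FALSE]
  }
  sub
}

#' Rank the strongest cell-type-specific interactions
#'
#' Reproduces the top-N strongest-interaction view: only edges whose ligand
#' shows cell-type-specific expression are kept — operationalised as the
#' ligand's maximum enrichment being at least `specificity_min` and attained
#' in the edge's sender population — then edges are ranked by strength
#' (descending), ties broken lexicographically by (ligand, receptor, sender,
#' receiver), and the top `n` returned.
#'
#' @param network An interaction network built on `profile`.
#' @param enrichment [enrichment_scores()] computed on the same profile.
#' @param n Number of interactions to return; default 50.
#' @param specificity_min Minimum ligand enrichment; default 2 (twice the
#'   cross-population mean).
#' @return Data frame of at most `n` edges with a `rank` column.
#' @export
rank_top_interactions <- function(network, enrichment, n = 50,
                                  specificity_min = 2.0) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(enrichment, "enrichment_matrix"))
  if (n <= 0) stop("n must be positive")
  edges <- network$edges
  if (nrow(edges) == 0) {
    return(cbind(edges, rank = integer()))
  }
  es <- enrichment$scores
  ok <- vapply(seq_len(nrow(edges)), function(i) {
    L <- edges$ligand[i]
    if (!(L %in% rownames(es))) return(FALSE)
    row <- es[L, ]
    mx <- max(row)
    mx >= specificity_min && row[edges$sender[i]] == mx
  }, logical(1))
  kept <- edges[ok, , drop = FALSE]
  ord <- order(-kept$strength, kept$ligand, kept$receptor, kept$sender,
               kept$receiver)
  kept <- kept[ord, , drop = FALSE]
  kept <- utils::head(kept, n)
  rownames(kept) <- NULL
  if (nrow(kept) > 0) kept$rank <- seq_len(nrow(kept)) else kept$rank <- integer()
  kept
}

#' Per-(sender, receiver) interaction count table
#'
#' The T x T table whose (s, r) cell counts the directed edges sent from
#' population s to population r; the grand total equals the number of edges.
#'
#' @param network An interaction network.
#' @return Integer matrix, rows = senders, columns = receivers.
#' @export
pairwise_count_table <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  network$pair_counts
}
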