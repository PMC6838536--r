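#' Construct an expression profile (genes x populations, FPKM)
#'
#' The substrate of all network inference: a non-negative matrix of bulk
#' expression values with one row per gene symbol and one column per sorted
#' cell population.
#'
#' @param values Numeric matrix, genes in rows, populations in columns.
#' @param gene_ids Character vector of unique gene symbols; defaults to
#'   `rownames(values)`.
#' @param type_ids Character vector of unique population names; defaults to
#'   `colnames(values)`.
#' @return An object of class `"expr_profile"` with elements `gene_ids`,
#'   `type_ids` and `values` (the matrix, carrying dimnames).
#' @examples
#' m <- matrix(c(10, 0, 40, 2, 5, 30), nrow = 3,
#'             dimnames = list(c("Apoe", "Kdr", "Vtn"), c("Mg", "EC")))
#' expression_profile(m)
#' @export
expression_profile <- function(values, gene_ids = rownames(values),
                               type_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(type_ids)) {
    stop("expression_profile needs gene and population names ",
         "(dimnames or explicit gene_ids/type_ids)")
  }
  gene_ids <- as.character(gene_ids)
  type_ids <- as.character(type_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(type_ids)) {
    stop("label lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene symbols: ", paste(utils::head(dups, 5), collapse = ", "))
  }
  if (anyDuplicated(type_ids)) stop("duplicate population names")
  if (length(type_ids) < 2) stop("an expression profile needs at least 2 populations")
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (any(!is.finite(values))) stop("expression values must all be finite (no NA/NaN/Inf)")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative FPKM value at gene '%s', population '%s'",
                 gene_ids[bad[1]], type_ids[bad[2]]))
  }
  dimnames(values) <- list(gene_ids, type_ids)
  structure(list(gene_ids = gene_ids, type_ids = type_ids, values = values),
            class = "expr_profile")
}

#' @export
print.expr_profile <- function(x, ...) {
  cat(sprintf("Expression profile: %d genes x %d populations (FPKM)\n",
              length(x$gene_ids), length(x$type_ids)))
  cat("Populations:", paste(x$type_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_profile <- function(x) dim(x$values)

#' Construct a ligand-receptor pair database
#'
#' A catalogue of directed (ligand gene, receptor gene) pairs in the dialect
#' of curated ligand-receptor resources: two gene-symbol columns, one row per
#' pair. Pairs are de-duplicated as ordered tuples; a gene may legitimately
#' appear as a ligand in one pair and a receptor in another.
#'
#' @param ligand,receptor Character vectors of equal length.
#' @param source_tag Free-text provenance recorded with the database.
#' @return An object of class `"lr_database"` with a `pairs` data frame
#'   (columns `ligand`, `receptor`) and `source_tag`.
#' @export
lr_database <- function(ligand, receptor, source_tag = "") {
  ligand <- as.character(ligand)
  receptor <- as.character(receptor)
  if (length(ligand) != length(receptor)) stop("ligand/receptor length mismatch")
  if (length(ligand) == 0) stop("empty ligand-receptor database")
  if (any(!nzchar(ligand)) || any(!nzchar(receptor))) {
    stop("empty gene symbol in ligand-receptor pair")
  }
  pairs <- unique(data.frame(ligand = ligand, receptor = receptor,
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, source_tag = source_tag), class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("Ligand-receptor database: %d unique pairs", nrow(x$pairs)))
  if (nzchar(x$source_tag)) cat(sprintf(" [%s]", x$source_tag))
  cat("\n")
  invisible(x)
}

#' Construct a labelled single-cell count matrix
#'
#' Genes x cells integer counts (UMI / unique-transcript units) with one
#' FACS-gate label per cell, the input of the gate-purity pipeline.
#'
#' @param counts Matrix or sparse Matrix of non-negative integer counts with
#'   gene rownames and cell colnames.
#' @param gate_labels Character vector of gate names, either named by cell id
#'   or in column order.
#' @return An object of class `"sc_matrix"` with elements `counts` (a base
#'   matrix), `gene_ids`, `cell_ids` and `gate_labels` (named by cell).
#' @export
single_cell_matrix <- function(counts, gate_labels) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (any(counts != round(counts))) stop("counts must be integers")
  labs <- unlist(gate_labels)
  gate_labels <- stats::setNames(as.character(labs), names(labs))
  if (!is.null(names(gate_labels))) {
    missing <- setdiff(colnames(counts), names(gate_labels))
    if (length(missing) > 0) {
      stop(sprintf("%d cells lack a gate label (e.g. %s); %d labels supplied",
                   length(missing), missing[1], length(gate_labels)))
    }
    gate_labels <- gate_labels[colnames(counts)]
  } else {
    if (length(gate_labels) != ncol(counts)) {
      stop(sprintf("label/cell mismatch: %d cells but %d gate labels",
                   ncol(counts), length(gate_labels)))
    }
    names(gate_labels) <- colnames(counts)
  }
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_ids = colnames(counts), gate_labels = gate_labels),
            class = "sc_matrix")
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat(sprintf("Single-cell matrix: %d genes x %d cells; gates: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$gate_labels)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sc_matrix <- function(x) dim(x$counts)

# Internal constructor; build_network() is the user-facing path.
interaction_network <- function(edges, populations, metadata = list()) {
  stopifnot(is.data.frame(edges))
  needed <- c("ligand", "receptor", "sender", "receiver", "strength")
  if (!all(needed %in% names(edges))) {
    stop("edge table must have columns ", paste(needed, collapse = ", "))
  }
  edges <- edges[, needed, drop = FALSE]
  populations <- as.character(populations)
  bad <- !(edges$sender %in% populations) | !(edges$receiver %in% populations)
  if (any(bad)) stop("edge references population outside the declared set")
  if (any(edges$strength < 0)) stop("edge strength must be non-negative")
  edges <- edges[order(edges$ligand, edges$receptor, edges$sender, edges$receiver), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  pc <- matrix(0L, length(populations), length(populations),
               dimnames = list(sender = populations, receiver = populations))
  if (nrow(edges) > 0) {
    tab <- table(factor(edges$sender, levels = populations),
                 factor(edges$receiver, levels = populations))
    pc[] <- as.integer(tab)
  }
  structure(list(edges = edges, populations = populations, pair_counts = pc,
                 unique_pair_count = nrow(unique(edges[, c("ligand", "receptor")])),
                 n_edges = nrow(edges), metadata = metadata),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d directed edges, %d unique ligand-receptor pairs, %d populations\n",
              x$n_edges, x$unique_pair_count, length(x$populations)))
  if (length(x$metadata)) {
    cat("Thresholds:",
        paste(sprintf("%s=%s", names(x$metadata), unlist(x$metadata)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Run the RNG at a fixed seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
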