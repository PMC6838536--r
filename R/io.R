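# Tabular dialect used throughout: tab-separated, UTF-8, header row required,
# decimal point only. No silent coercion: malformed cells raise errors.

read_tsv_strict <- function(source) {
  df <- utils::read.delim(source, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty table")
  df
}

#' Read a genes x populations expression table
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose remaining columns hold numeric FPKM values, one per population.
#'
#' @param source File path or connection.
#' @param fpkm_column_map Optional named character vector renaming file
#'   columns to population names (`c(file_col = "population")`).
#' @param duplicate_policy `"strict"` (default) errors on duplicated gene
#'   symbols; `"collapse"` averages their rows. Silent averaging of symbol
#'   collisions is deliberately opt-in.
#' @return An [expression_profile()].
#' @export
read_expression_table <- function(source, fpkm_column_map = NULL,
                                  duplicate_policy = c("strict", "collapse")) {
  duplicate_policy <- match.arg(duplicate_policy)
  df <- read_tsv_strict(source)
  if (ncol(df) < 3) stop("expression table needs a gene column and >= 2 populations")
  genes <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  if (!is.null(fpkm_column_map)) {
    hit <- names(vals) %in% names(fpkm_column_map)
    names(vals)[hit] <- unname(fpkm_column_map[names(vals)[hit]])
  }
  mat <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(NULL, names(vals)))
  for (j in seq_len(ncol(vals))) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x) & !is.na(vals[[j]]))
    if (length(bad) > 0 || anyNA(vals[[j]])) {
      i <- if (length(bad) > 0) bad[1] else which(is.na(vals[[j]]))[1]
      stop(sprintf("non-numeric expression value '%s' at row %d (gene '%s'), column '%s'",
                   vals[[j]][i], i, genes[i], names(vals)[j]))
    }
    mat[, j] <- x
  }
  if (anyDuplicated(genes)) {
    if (duplicate_policy == "strict") {
      dups <- unique(genes[duplicated(genes)])
      stop("duplicate gene symbols (use duplicate_policy = \"collapse\" to average): ",
           paste(utils::head(dups, 5), collapse = ", "))
    }
    mat <- rowsum(mat, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(mat) <- genes
  expression_profile(mat)
}

#' Write an expression profile as a TSV table
#'
#' @param profile An [expression_profile()].
#' @param path Output file path; first column `gene`, then one column per
#'   population.
#' @export
write_expression_table <- function(profile, path) {
  stopifnot(inherits(profile, "expr_profile"))
  df <- data.frame(gene = profile$gene_ids, profile$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' One row per curated pair; two gene-symbol columns. Default column names
#' follow the curated-catalogue dialect (`Ligand.ApprovedSymbol`,
#' `Receptor.ApprovedSymbol`), with plain `ligand`/`receptor` accepted as a
#' fallback.
#'
#' @param source File path or connection (TSV with header).
#' @param ligand_col,receptor_col Column names holding the symbols.
#' @param source_tag Provenance string stored in the database.
#' @return An [lr_database()]; duplicated rows are collapsed and the retained
#'   count reported via message.
#' @export
read_lr_pairs <- function(source, ligand_col = "Ligand.ApprovedSymbol",
                          receptor_col = "Receptor.ApprovedSymbol",
                          source_tag = NULL) {
  df <- read_tsv_strict(source)
  pick <- function(wanted, fallback) {
    if (wanted %in% names(df)) return(wanted)
    if (fallback %in% names(df)) return(fallback)
    stop(sprintf("column '%s' not found; available columns: %s",
                 wanted, paste(names(df), collapse = ", ")))
  }
  lc <- pick(ligand_col, "ligand")
  rc <- pick(receptor_col, "receptor")
  db <- lr_database(df[[lc]], df[[rc]],
                    source_tag = if (is.null(source_tag))
                      paste0("read from ", paste(as.character(source), collapse = ""))
                    else source_tag)
  message(sprintf("read %d rows, retained %d unique ligand-receptor pairs",
                  nrow(df), nrow(db$pairs)))
  db
}

#' Write a ligand-receptor database as TSV
#' @param db An [lr_database()].
#' @param path Output path; columns `ligand`, `receptor`.
#' @export
write_lr_pairs <- function(db, path) {
  stopifnot(inherits(db, "lr_database"))
  utils::write.table(db$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a single-cell count matrix with gate labels
#'
#' Accepts either a dense TSV (first column gene symbols, one column per
#' cell) or a MatrixMarket triplet file accompanied by row (gene) and column
#' (cell) name files, one name per line. Gate labels come from a two-column
#' TSV (`cell`, `gate`).
#'
#' @param source Path to the dense TSV or `.mtx` file.
#' @param gate_labels Path to the cell/gate TSV, or a named character vector.
#' @param genes,cells For MTX input: paths to the row/column name files.
#' @param unlabelled `"error"` (default) rejects cells without a gate label;
#'   `"drop"` removes them with a message.
#' @return A [single_cell_matrix()].
#' @export
read_count_matrix <- function(source, gate_labels, genes = NULL, cells = NULL,
                              unlabelled = c("error", "drop")) {
  unlabelled <- match.arg(unlabelled)
  if (grepl("\\.mtx$", source)) {
    m <- as.matrix(Matrix::readMM(source))
    if (is.null(genes) || is.null(cells)) {
      stop("MTX input needs 'genes' and 'cells' name files")
    }
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(cells)
  } else {
    df <- read_tsv_strict(source)
    m <- as.matrix(vapply(df[-1], function(x) as.numeric(x), numeric(nrow(df))))
    if (nrow(df) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)[-1]))
    rownames(m) <- df[[1]]
  }
  if (is.character(gate_labels) && length(gate_labels) == 1 &&
      file.exists(gate_labels)) {
    lab <- read_tsv_strict(gate_labels)
    labels <- stats::setNames(lab[[2]], lab[[1]])
  } else {
    labels <- gate_labels
  }
  unlab <- setdiff(colnames(m), names(labels))
  if (length(unlab) > 0 && unlabelled == "drop") {
    message(sprintf("dropping %d unlabelled cells", length(unlab)))
    m <- m[, setdiff(colnames(m), unlab), drop = FALSE]
  }
  out <- single_cell_matrix(m, labels)
  message(sprintf("count matrix: %d genes x %d cells", nrow(m), ncol(m)))
  out
}

#' Write a single-cell matrix as MatrixMarket triplet plus sidecar files
#'
#' Writes `<prefix>.mtx`, `<prefix>.genes.txt`, `<prefix>.cells.txt` and
#' `<prefix>.gates.tsv`.
#'
#' @param mat A [single_cell_matrix()].
#' @param prefix Output path prefix.
#' @export
write_count_matrix <- function(mat, prefix) {
  stopifnot(inherits(mat, "sc_matrix"))
  Matrix::writeMM(Matrix::Matrix(mat$counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(mat$gene_ids, paste0(prefix, ".genes.txt"))
  writeLines(mat$cell_ids, paste0(prefix, ".cells.txt"))
  utils::write.table(data.frame(cell = mat$cell_ids,
                                gate = unname(mat$gate_labels[mat$cell_ids])),
                     paste0(prefix, ".gates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

#' Write an interaction network
#'
#' Two formats: a flat edge list (TSV with columns ligand, receptor, sender,
#' receiver, strength) or the explorer JSON contract carrying population
#' nodes, gene nodes with enrichment vectors, and directed edges.
#'
#' @param network An interaction network from [build_network()].
#' @param path Output path.
#' @param format `"edgelist"` or `"json"`.
#' @param enrichment Optional enrichment matrix (from [enrichment_scores()])
#'   embedded in the JSON gene nodes.
#' @export
write_network <- function(network, path, format = c("edgelist", "json"),
                          enrichment = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    genes <- sort(unique(c(network$edges$ligand, network$edges$receptor)))
    gene_nodes <- lapply(genes, function(g) {
      node <- list(id = g)
      if (!is.null(enrichment) && g %in% rownames(enrichment$scores)) {
        node$enrichment <- as.list(enrichment$scores[g, ])
      }
      node
    })
    obj <- list(
      populations = as.list(network$populations),
      genes = gene_nodes,
      edges = network$edges,
      pair_counts = as.data.frame(as.table(network$pair_counts),
                                  responseName = "count"),
      unique_pair_count = network$unique_pair_count,
      n_edges = network$n_edges,
      metadata = network$metadata
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Read an interaction network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"edgelist"` or `"json"`.
#' @param populations Population set; required for the edge-list format
#'   (edge lists do not record populations that carry no edges).
#' @return An interaction network object.
#' @export
read_network <- function(path, format = c("edgelist", "json"),
                         populations = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(rep("character", 4), "numeric"))
    if (is.null(populations)) {
      populations <- sort(unique(c(df$sender, df$receiver)))
    }
    interaction_network(df, populations)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
    if (nrow(edges) == 0) {
      edges <- data.frame(ligand = character(), receptor = character(),
                          sender = character(), receiver = character(),
                          strength = numeric())
    }
    interaction_network(edges, unlist(obj$populations),
                        metadata = as.list(obj$metadata))
  }
}
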