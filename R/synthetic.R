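# Synthetic inputs with planted ground truth. The generators share one gene
# universe (markers, ligands, receptors, background, silent decoys) so marker
# panels carry over between the bulk and single-cell simulators.

default_types <- function(n_types) {
  base <- c("neural", "mural", "endothelial", "microglia")
  if (n_types <= length(base)) base[seq_len(n_types)]
  else c(base, paste0("type", seq_len(n_types - length(base))))
}

make_universe <- function(types, n_genes, markers_per_type, planted_pairs) {
  n_types <- length(types)
  n_special <- n_types * markers_per_type + 2 * planted_pairs
  if (n_special + 2 * planted_pairs > n_genes) {
    stop(sprintf("n_genes = %d cannot hold %d markers + %d planted ligand/receptor genes + decoys",
                 n_genes, n_types * markers_per_type, 2 * planted_pairs))
  }
  markers <- stats::setNames(
    lapply(seq_along(types), function(i)
      sprintf("MK%s_%02d", i, seq_len(markers_per_type))),
    types)
  ligands <- sprintf("LIG%03d", seq_len(planted_pairs))
  receptors <- sprintf("REC%03d", seq_len(planted_pairs))
  decoy_l <- sprintf("DLIG%03d", seq_len(planted_pairs))
  decoy_r <- sprintf("DREC%03d", seq_len(planted_pairs))
  n_bg <- n_genes - n_special - 2 * planted_pairs
  background <- sprintf("BG%04d", seq_len(n_bg))
  list(markers = markers, ligands = ligands, receptors = receptors,
       decoy_l = decoy_l, decoy_r = decoy_r, background = background,
       all = c(unlist(markers, use.names = FALSE), ligands, receptors,
               decoy_l, decoy_r, background))
}

# Noise-free mean FPKM profile for every gene in every type.
mean_profile <- function(universe, types, base_fpkm, low_fpkm, bg_fpkm,
                         senders, receivers) {
  genes <- universe$all
  mu <- matrix(low_fpkm, length(genes), length(types),
               dimnames = list(genes, types))
  for (t in types) mu[universe$markers[[t]], t] <- base_fpkm
  for (i in seq_along(universe$ligands)) {
    mu[universe$ligands[i], senders[i]] <- base_fpkm
    mu[universe$receptors[i], receivers[i]] <- base_fpkm
  }
  mu[universe$background, ] <- bg_fpkm
  # decoy ligand/receptor genes stay at low_fpkm everywhere: catalogued
  # pairs that must never pass the expression calls
  mu
}

#' Simulate a bulk expression profile with planted communication structure
#'
#' Generates a genes x populations FPKM matrix holding population-specific
#' marker genes, planted ligand-receptor pairs with designated sender and
#' receiver populations, near-uniform background genes and silent decoy
#' pairs, then applies multiplicative lognormal noise. The planted ligands
#' and receptors sit at `base_fpkm` in their designated populations and at
#' `low_fpkm` (default 0.5, well under any expression call) elsewhere, so
#' with no noise the expressed/not-expressed pattern is deterministic and
#' matches the returned truth exactly. The binding detection constraint for
#' a gene expressed in a single one of T populations is the mean filter
#' (T x `min_mean`, i.e. 40 FPKM at the defaults); the default
#' `base_fpkm = 200` places planted genes five-fold above it (and
#' twenty-fold above the per-type call).
#'
#' @param n_types Number of populations; default 4 (neural, mural,
#'   endothelial, microglia).
#' @param n_genes Total genes in the universe.
#' @param markers_per_type Marker genes planted per population.
#' @param planted_pairs Number of ligand-receptor pairs planted (each with
#'   one sender and one receiver, cycled over the populations; autocrine
#'   assignments occur when the cycle aligns).
#' @param base_fpkm On-target expression of planted genes.
#' @param low_fpkm Off-target expression of planted genes.
#' @param bg_fpkm Level of background genes (uniform across populations).
#' @param noise_sd Standard deviation of the lognormal factor on the log
#'   scale; 0 disables noise.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `profile` ([expression_profile()]), `lrdb`
#'   ([lr_database()] containing the planted pairs plus silent decoy pairs),
#'   and `truth` (class `"synthetic_truth"`: `marker_genes`, `planted_edges`
#'   data frame, `seed`).
#' @export
generate_bulk <- function(n_types = 4, n_genes = 200, markers_per_type = 10,
                          planted_pairs = 10, base_fpkm = 200, low_fpkm = 0.5,
                          bg_fpkm = 20, noise_sd = 0, seed = 1) {
  stopifnot(n_types >= 2, n_genes > 0, markers_per_type > 0,
            planted_pairs > 0, base_fpkm > 0, noise_sd >= 0)
  types <- default_types(n_types)
  universe <- make_universe(types, n_genes, markers_per_type, planted_pairs)
  senders <- types[(seq_len(planted_pairs) - 1) %% n_types + 1]
  receivers <- types[seq_len(planted_pairs) %% n_types + 1]
  mu <- mean_profile(universe, types, base_fpkm, low_fpkm, bg_fpkm,
                     senders, receivers)
  vals <- with_seed(seed, {
    if (noise_sd > 0) mu * exp(matrix(stats::rnorm(length(mu), 0, noise_sd),
                                      nrow(mu), ncol(mu)))
    else mu
  })
  dimnames(vals) <- dimnames(mu)
  lrdb <- lr_database(c(universe$ligands, universe$decoy_l),
                      c(universe$receptors, universe$decoy_r),
                      source_tag = "synthetic planted catalogue")
  truth <- structure(
    list(marker_genes = universe$markers,
         planted_edges = data.frame(ligand = universe$ligands,
                                    receptor = universe$receptors,
                                    sender = senders, receiver = receivers,
                                    stringsAsFactors = FALSE),
         contamination = NULL, seed = seed),
    class = "synthetic_truth")
  list(profile = expression_profile(vals), lrdb = lrdb, truth = truth)
}

#' Simulate a labelled single-cell count matrix with gate contamination
#'
#' Each cell carries a FACS-gate label; its true identity equals the gate
#' with probability 1 - contamination[gate], otherwise a uniformly chosen
#' other population. Counts are negative binomial around type-specific mean
#' profiles (markers high in the home type), with per-cell sequencing depth
#' drawn lognormal around `depth_mean` so that a transcript-count filter has
#' cells on both sides of any realistic threshold.
#'
#' @param n_types Number of populations / gates; default 4.
#' @param cells_per_gate Cells sorted into each gate.
#' @param n_genes Genes in the shared universe.
#' @param markers_per_type Markers per population.
#' @param depth_mean Mean per-cell total transcript count.
#' @param depth_sd_log Lognormal sd of per-cell depth (log scale).
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed), common to the whole run.
#' @param contamination Either a single fraction in [0, 1) applied to every
#'   gate or a named vector per gate.
#' @param seed Integer seed.
#' @return List with `matrix` (a [single_cell_matrix()]) and `truth`
#'   (class `"synthetic_truth"` with `marker_genes`, `true_identity` named by
#'   cell, `contamination`, `seed`).
#' @export
generate_single_cell <- function(n_types = 4, cells_per_gate = 100,
                                 n_genes = 200, markers_per_type = 10,
                                 depth_mean = 3000, depth_sd_log = 0.35,
                                 nb_dispersion = 2, contamination = 0,
                                 seed = 1) {
  stopifnot(n_types >= 2, cells_per_gate > 0, depth_mean > 0,
            nb_dispersion > 0)
  types <- default_types(n_types)
  if (length(contamination) == 1 && is.null(names(contamination))) {
    contamination <- stats::setNames(rep(contamination, n_types), types)
  }
  if (any(contamination < 0) || any(contamination >= 1)) {
    stop("contamination fractions must lie in [0, 1)")
  }
  universe <- make_universe(types, n_genes, markers_per_type, 1)
  # relative expression programme per type: markers dominate their home type
  mu <- mean_profile(universe, types, base_fpkm = 50, low_fpkm = 0.5,
                     bg_fpkm = 20, senders = types[1], receivers = types[2])
  prog <- sweep(mu, 2, colSums(mu), "/")
  gates <- rep(types, each = cells_per_gate)
  n_cells <- length(gates)
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  out <- with_seed(seed, {
    true_id <- vapply(gates, function(g) {
      if (stats::runif(1) < contamination[g]) sample(setdiff(types, g), 1) else g
    }, character(1), USE.NAMES = FALSE)
    depth <- stats::rlnorm(n_cells, log(depth_mean), depth_sd_log)
    counts <- matrix(0L, nrow(prog), n_cells,
                     dimnames = list(rownames(prog), cell_ids))
    for (j in seq_len(n_cells)) {
      counts[, j] <- stats::rnbinom(nrow(prog), size = nb_dispersion,
                                    mu = depth[j] * prog[, true_id[j]])
    }
    list(counts = counts, true_id = true_id)
  })
  mat <- single_cell_matrix(out$counts, stats::setNames(gates, cell_ids))
  truth <- structure(
    list(marker_genes = universe$markers,
         true_identity = stats::setNames(out$true_id, cell_ids),
         contamination = contamination, seed = seed),
    class = "synthetic_truth")
  list(matrix = mat, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:",
      length(unlist(x$marker_genes)), "planted markers")
  if (!is.null(x$planted_edges)) cat(";", nrow(x$planted_edges), "planted edges")
  if (!is.null(x$true_identity)) cat(";", length(x$true_identity), "cells")
  cat("; seed", x$seed, "\n")
  invisible(x)
}

#' Emulate shallow single-cell detection by expression-dependent dropout
#'
#' Zeroes whole gene rows of a bulk profile with probability
#' `exp(-mean_fpkm / scale)`, so lowly expressed genes are preferentially
#' lost while strongly expressed genes usually survive — the qualitative
#' detection behaviour of shallow single-cell protocols relative to bulk
#' sequencing. Applying it to any profile can only remove, never add,
#' detectable genes.
#'
#' @param profile An [expression_profile()].
#' @param scale Mean FPKM at which a gene survives with probability
#'   1 - 1/e; default 50.
#' @param seed Integer seed.
#' @return The thinned [expression_profile()].
#' @export
simulate_dropout <- function(profile, scale = 50, seed = 1) {
  stopifnot(inherits(profile, "expr_profile"), scale > 0)
  vals <- profile$values
  p_drop <- exp(-rowMeans(vals) / scale)
  drop <- with_seed(seed, stats::runif(nrow(vals)) < p_drop)
  vals[drop, ] <- 0
  expression_profile(vals)
}
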