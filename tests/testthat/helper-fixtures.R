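# Shared fixtures and independent oracles.

# A small hand-built profile: 4 populations, genes spanning the boundary
# cases of the mean filter and the per-type call.
toy_profile <- function() {
  m <- rbind(
    Apoe  = c(2, 1, 3, 400),    # microglial ligand
    Lrp1  = c(50, 12, 60, 8),   # broadly expressed receptor
    Vtn   = c(0, 300, 2, 1),    # mural ligand
    Kdr   = c(0, 0, 150, 0),    # endothelial receptor
    Flat  = c(10, 10, 10, 10),  # mean exactly at the default cutoff
    Edge  = c(0, 0, 0, 41),     # mean 10.25, single-type expression
    Off   = c(1, 2, 1, 1)       # below every threshold
  )
  colnames(m) <- c("neural", "mural", "endothelial", "microglia")
  expression_profile(m)
}

toy_lrdb <- function() {
  lr_database(ligand = c("Apoe", "Apoe", "Vtn", "Ghost"),
              receptor = c("Lrp1", "Kdr", "Kdr", "Nothere"),
              source_tag = "toy")
}

# Independent brute-force network oracle: plain loops and arithmetic, no
# calls into the code path under test.
brute_force_network <- function(values, pairs, per_type_min = 10,
                                min_mean = 10) {
  types <- colnames(values)
  keep <- apply(values, 1, function(row) sum(row) / length(row) > min_mean)
  values <- values[keep, , drop = FALSE]
  out <- data.frame(ligand = character(), receptor = character(),
                    sender = character(), receiver = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    L <- pairs$ligand[i]; R <- pairs$receptor[i]
    if (!(L %in% rownames(values)) || !(R %in% rownames(values))) next
    for (s in types) for (r in types) {
      if (values[L, s] >= per_type_min && values[R, r] >= per_type_min) {
        out <- rbind(out, data.frame(ligand = L, receptor = R, sender = s,
                                     receiver = r, stringsAsFactors = FALSE))
      }
    }
  }
  unique(out)
}

edge_keys <- function(edges) {
  sort(paste(edges$ligand, edges$receptor, edges$sender, edges$receiver,
             sep = "|"))
}

# Random instance for oracle-equivalence checks.
random_instance <- function(n_genes, n_pairs, n_types) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  types <- sprintf("P%d", seq_len(n_types))
  vals <- matrix(stats::rexp(n_genes * n_types, rate = 1 / 15),
                 n_genes, n_types, dimnames = list(genes, types))
  pairs <- data.frame(ligand = sample(genes, n_pairs, replace = TRUE),
                      receptor = sample(genes, n_pairs, replace = TRUE),
                      stringsAsFactors = FALSE)
  list(profile = expression_profile(vals),
       pairs = unique(pairs))
}

make_planted_edge_keys <- function(truth) {
  with(truth$planted_edges,
       sort(paste(ligand, receptor, sender, receiver, sep = "|")))
}

write_tsv_text <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
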