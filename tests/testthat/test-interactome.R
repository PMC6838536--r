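test_that("mean filter retains strictly-above-threshold genes only", {
  p <- toy_profile()
  kept <- filter_expressed_genes(p, 10)
  expect_false("Flat" %in% kept$gene_ids) # mean exactly 10
  expect_true("Edge" %in% kept$gene_ids)  # mean 10.25
  expect_false("Off" %in% kept$gene_ids)
  # oracle: recompute means by hand on a random profile
  set.seed(1)
  inst <- random_instance(80, 5, 4)
  kept2 <- filter_expressed_genes(inst$profile, 10)
  manual <- rownames(inst$profile$values)[
    apply(inst$profile$values, 1, function(r) sum(r) / length(r) > 10)]
  expect_setequal(kept2$gene_ids, manual)
})

test_that("enrichment scores are expression over cross-population mean", {
  m <- rbind(flat = c(10, 10, 10, 10),
             solo = c(40, 0, 0, 0),
             mix  = c(30, 10, 20, 40))
  colnames(m) <- paste0("P", 1:4)
  enr <- enrichment_scores(expression_profile(m))
  expect_equal(unname(enr$scores["flat", ]), c(1, 1, 1, 1))
  expect_equal(unname(enr$scores["solo", ]), c(4, 0, 0, 0))
  expect_equal(unname(enr$scores["mix", ]), c(1.2, 0.4, 0.8, 1.6))
})

test_that("zero-mean genes are dropped from enrichment with a warning", {
  m <- rbind(a = c(1, 2), b = c(0, 0))
  colnames(m) <- c("P1", "P2")
  expect_warning(enr <- enrichment_scores(expression_profile(m)),
                 "zero mean")
  expect_equal(rownames(enr$scores), "a")
})

test_that("per-gene mean enrichment is 1 on random profiles", {
  set.seed(2)
  for (rep in 1:20) {
    inst <- random_instance(50, 5, sample(2:6, 1))
    enr <- suppressWarnings(enrichment_scores(inst$profile))
    expect_lt(max(abs(rowMeans(enr$scores) - 1)), 1e-9)
  }
})

test_that("expression calls threshold at >= per-type minimum", {
  m <- rbind(g = c(12, 3, 15, 0))
  colnames(m) <- paste0("P", 1:4)
  calls <- call_expression(expression_profile(m), 10)
  expect_equal(unname(calls$calls["g", ]), c(TRUE, FALSE, TRUE, FALSE))
  # threshold 0: every non-negative entry is called, including exact zeros
  expect_true(all(call_expression(expression_profile(m), 0)$calls))
  set.seed(3)
  inst <- random_instance(40, 5, 4)
  expect_equal(call_expression(inst$profile, 7)$calls,
               inst$profile$values >= 7)
})

test_that("network construction enumerates sender x receiver combinations", {
  m <- rbind(L1 = c(100, 2), R1 = c(60, 50), Bg = c(30, 30))
  colnames(m) <- c("A", "B")
  net <- build_network(expression_profile(m), lr_database("L1", "R1"))
  expect_equal(edge_keys(net$edges),
               c("L1|R1|A|A", "L1|R1|A|B"))
  expect_equal(net$unique_pair_count, 1)
  expect_equal(unname(net$pair_counts["A", ]), c(1L, 1L))
  expect_equal(unname(net$pair_counts["B", ]), c(0L, 0L))

  # ligand in 2 types x receptor in 2 types -> 4 directed edges, 1 pair
  m2 <- rbind(L = c(50, 50, 1, 1), R = c(1, 40, 40, 1))
  colnames(m2) <- paste0("P", 1:4)
  net2 <- build_network(expression_profile(m2), lr_database("L", "R"))
  expect_equal(net2$n_edges, 4)
  expect_equal(net2$unique_pair_count, 1)
})

test_that("edge strength modes agree with their formulas", {
  m <- rbind(L = c(90, 1), R = c(1, 40))
  colnames(m) <- c("A", "B")
  p <- expression_profile(m)
  db <- lr_database("L", "R")
  expect_equal(build_network(p, db, strength = "geomean")$edges$strength,
               sqrt(90 * 40))
  expect_equal(build_network(p, db, strength = "min")$edges$strength, 40)
  expect_equal(build_network(p, db, strength = "sum")$edges$strength, 130)
  expect_equal(build_network(p, db, strength = "product")$edges$strength, 3600)
})

test_that("build_network matches the brute-force oracle on random instances", {
  set.seed(4)
  for (rep in 1:25) {
    inst <- random_instance(sample(20:200, 1), sample(5:50, 1), sample(2:6, 1))
    db <- lr_database(inst$pairs$ligand, inst$pairs$receptor)
    net <- suppressWarnings(suppressMessages(build_network(inst$profile, db)))
    oracle <- brute_force_network(inst$profile$values, inst$pairs)
    expect_identical(edge_keys(net$edges), edge_keys(oracle))
  }
})

test_that("raising either threshold never adds edges", {
  set.seed(5)
  inst <- random_instance(120, 30, 4)
  db <- lr_database(inst$pairs$ligand, inst$pairs$receptor)
  count_at <- function(ptm, mm) suppressWarnings(suppressMessages(
    build_network(inst$profile, db, per_type_min = ptm, min_mean = mm)))$n_edges
  base <- count_at(10, 10)
  for (ptm in c(12, 15, 25)) expect_lte(count_at(ptm, 10), base)
  for (mm in c(12, 15, 25)) expect_lte(count_at(10, mm), base)
  # and edge sets are nested, not merely smaller
  lo <- suppressWarnings(suppressMessages(build_network(inst$profile, db, 10, 10)))
  hi <- suppressWarnings(suppressMessages(build_network(inst$profile, db, 20, 15)))
  expect_true(all(edge_keys(hi$edges) %in% edge_keys(lo$edges)))
})

test_that("empty catalogue is an error; absent genes are skipped silently", {
  p <- toy_profile()
  expect_error(build_network(p, structure(list(pairs = data.frame()),
                                          class = "lr_database")),
               "empty ligand-receptor database")
  expect_message(build_network(p, toy_lrdb()), "skipped")
})

test_that("subnetworks slice by receptor or ligand and carry enrichment rows", {
  p <- toy_profile()
  net <- suppressMessages(build_network(p, toy_lrdb()))
  enr <- enrichment_scores(filter_expressed_genes(p))
  rsub <- subnetwork(net, "Kdr", "receptor", enrichment = enr)
  expect_true(all(rsub$edges$receptor == "Kdr"))
  expect_setequal(sort(unique(rsub$edges$ligand)), c("Apoe", "Vtn"))
  expect_true(all(rownames(rsub$heatmap) %in%
                    c(rsub$edges$ligand, rsub$edges$receptor)))

  lsub <- subnetwork(net, "Apoe", "ligand")
  expect_true(all(lsub$edges$ligand == "Apoe"))

  expect_warning(subnetwork(net, "Kdr", "ligand"), "no edges")
  expect_error(subnetwork(net, "Kdrr", "receptor"), "near matches.*Kdr")
})

test_that("top-interaction ranking filters on ligand specificity in the sender", {
  p <- toy_profile()
  net <- suppressMessages(build_network(p, toy_lrdb()))
  enr <- enrichment_scores(filter_expressed_genes(p))
  ranked <- rank_top_interactions(net, enr, n = 50, specificity_min = 2)
  # Apoe and Vtn are single-type ligands; every kept edge must send from
  # the population where their enrichment peaks
  expect_true(all(ranked$sender[ranked$ligand == "Apoe"] == "microglia"))
  expect_true(all(ranked$sender[ranked$ligand == "Vtn"] == "mural"))
  expect_equal(ranked$strength, sort(ranked$strength, decreasing = TRUE))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_error(rank_top_interactions(net, enr, n = 0), "positive")

  # a ubiquitous ligand is excluded no matter how high its expression
  m <- rbind(Ubi = c(5000, 5000, 5000, 5000), R = c(100, 1, 1, 1))
  colnames(m) <- p$type_ids
  p2 <- expression_profile(m)
  net2 <- build_network(p2, lr_database("Ubi", "R"))
  expect_gt(net2$n_edges, 0)
  expect_equal(nrow(rank_top_interactions(net2, enrichment_scores(p2),
                                          specificity_min = 2)), 0)
})

test_that("ranking equals an independent sort of recomputed strengths", {
  sim <- generate_bulk(noise_sd = 0.25, seed = 21)
  net <- suppressMessages(build_network(sim$profile, sim$lrdb))
  enr <- suppressWarnings(enrichment_scores(
    filter_expressed_genes(sim$profile)))
  ranked <- rank_top_interactions(net, enr, n = 10)
  vals <- sim$profile$values
  manual <- sqrt(vals[cbind(ranked$ligand, ranked$sender)] *
                   vals[cbind(ranked$receptor, ranked$receiver)])
  expect_equal(ranked$strength, unname(manual))
  expect_equal(ranked$strength, sort(ranked$strength, decreasing = TRUE))
})

test_that("pairwise counts conserve the edge total", {
  set.seed(6)
  for (rep in 1:10) {
    inst <- random_instance(100, 25, 4)
    db <- lr_database(inst$pairs$ligand, inst$pairs$receptor)
    net <- suppressWarnings(suppressMessages(build_network(inst$profile, db)))
    tab <- pairwise_count_table(net)
    expect_equal(sum(tab), net$n_edges)
    expect_lte(net$unique_pair_count, net$n_edges)
    # brute-force tally
    manual <- table(factor(net$edges$sender, levels = net$populations),
                    factor(net$edges$receiver, levels = net$populations))
    expect_equal(unname(as.integer(manual)), unname(as.vector(tab)))
  }
})

test_that("unique pairs equal edges exactly when each pair has one combination", {
  m <- rbind(L1 = c(100, 1), R1 = c(1, 100),
             L2 = c(1, 100), R2 = c(100, 1))
  colnames(m) <- c("A", "B")
  net <- build_network(expression_profile(m),
                       lr_database(c("L1", "L2"), c("R1", "R2")))
  expect_equal(net$n_edges, net$unique_pair_count)
})

test_that("noiseless simulation is recovered exactly; noisy within tolerance", {
  sim <- generate_bulk(planted_pairs = 8, noise_sd = 0, seed = 31)
  net <- suppressMessages(build_network(sim$profile, sim$lrdb))
  expect_identical(edge_keys(net$edges), make_planted_edge_keys(sim$truth))
})

test_that("dropout of low-expressed genes strictly reduces the edge count", {
  sim <- generate_bulk(planted_pairs = 12, noise_sd = 0.3, seed = 41)
  full <- suppressMessages(build_network(sim$profile, sim$lrdb))
  thin <- suppressWarnings(suppressMessages(
    build_network(simulate_dropout(sim$profile, seed = 41), sim$lrdb)))
  expect_lt(thin$n_edges, full$n_edges)
  # dropout favours lowly expressed genes: survivors are richer in
  # high-mean genes than casualties
  thinned <- simulate_dropout(sim$profile, seed = 41)
  lost <- rowMeans(thinned$values) == 0 & rowMeans(sim$profile$values) > 0
  expect_gt(mean(rowMeans(sim$profile$values)[!lost]),
            mean(rowMeans(sim$profile$values)[lost]))
})
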