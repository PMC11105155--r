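test_that("genome simulation is deterministic, GC-accurate and validated", {
  g1 <- simulate_genome(2, c(5000, 3000), gc = 0.4, seed = 6)
  g2 <- simulate_genome(2, c(5000, 3000), gc = 0.4, seed = 6)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- simulate_genome(2, c(5000, 3000), gc = 0.4, seed = 7)
  expect_false(identical(as.character(g1), as.character(g3)))

  big <- simulate_genome(1, 1e6, gc = 0.5, seed = 2)
  gc_obs <- sum(Biostrings::letterFrequency(big, c("G", "C"))) / 1e6
  expect_lt(abs(gc_obs - 0.5), 0.005)

  low <- simulate_genome(1, 2e5, gc = 0.3, seed = 2)
  gc_low <- sum(Biostrings::letterFrequency(low, c("G", "C"))) / 2e5
  expect_lt(abs(gc_low - 0.3), 0.01)

  expect_error(simulate_genome(1, 0), "positive")
  expect_error(simulate_genome(1, 1000, gc = 1.2), "gc")

  # the i.i.d. variant is available and GC-accurate too
  iid <- simulate_genome(1, 2e5, gc = 0.5, seed = 3, dinuc_bias = NULL)
  gc_iid <- sum(Biostrings::letterFrequency(iid, c("G", "C"))) / 2e5
  expect_lt(abs(gc_iid - 0.5), 0.01)
})

test_that("background model depresses TpA and boosts CpA/TpG", {
  g <- simulate_genome(1, 3e5, gc = 0.5, seed = 10)
  idx <- rip_indices(count_dinucleotides(g[[1]]))
  # un-RIPped background: product index well below 1, substrate above 1,
  # composite clearly negative
  expect_lt(idx[["product_index"]], 0.9)
  expect_gt(idx[["substrate_index"]], 1.05)
  expect_lt(idx[["composite_index"]], -0.15)
  # whereas the memoryless model is symmetric around composite 0
  g_iid <- simulate_genome(1, 3e5, gc = 0.5, seed = 10, dinuc_bias = NULL)
  idx_iid <- rip_indices(count_dinucleotides(g_iid[[1]]))
  expect_lt(abs(idx_iid[["composite_index"]]), 0.05)
})

test_that("RIP planting follows the CpA/TpG rule and its edge cases", {
  g <- simulate_genome(1, 20000, seed = 20)
  win <- data.frame(contig = "contig_1", start = 1000, end = 3000)

  r0 <- plant_rip(g, win, rate = 0, seed = 1)
  expect_identical(as.character(r0$genome), as.character(g))

  r1 <- plant_rip(g, win, rate = 1, seed = 1)
  inside <- substr(as.character(r1$genome)[[1]], 1001, 3000)
  d <- count_dinucleotides(inside)
  expect_equal(d[["CA"]], 0L)
  expect_equal(d[["TG"]], 0L)
  # outside the window nothing changed
  expect_identical(substr(as.character(r1$genome)[[1]], 1, 1000),
                   substr(as.character(g)[[1]], 1, 1000))
  expect_identical(substr(as.character(r1$genome)[[1]], 3001, 20000),
                   substr(as.character(g)[[1]], 3001, 20000))
  expect_gt(r1$truth$n_mutated, 0)

  # planted windows beat background on the composite index
  r5 <- plant_rip(g, win, rate = 0.5, seed = 2)
  w <- scan_windows(r5$genome)
  planted <- w$composite_index[w$start >= 1000 & w$end <= 3000]
  background <- w$composite_index[w$start >= 4000]
  expect_gt(min(planted, na.rm = TRUE), max(background, na.rm = TRUE))

  expect_error(plant_rip(g, data.frame(contig = "contig_1", start = c(0, 500),
                                       end = c(1000, 1500)), 0.5),
               "overlap")
  expect_error(plant_rip(g, data.frame(contig = "contig_1", start = 19500,
                                       end = 20500), 0.5), "bounds")
  expect_error(plant_rip(g, win, rate = 2), "rate")
})

test_that("domain table simulation plants multiplicative enrichments", {
  enr <- tibble::tibble(species = "sp01", domain_id = "dom0001", fold = 5)
  sim <- simulate_domain_tables(n_species = 3, n_domains = 30, totals = 5000,
                                base_mean = 40, enrichments = enr, seed = 14)
  m <- build_count_matrix(sim$table)
  # planted cell is Poisson(200): comfortably above the Poisson(40) baseline
  expect_gt(m$counts["sp01", "dom0001"], 120)
  base_cells <- m$counts[, colnames(m$counts) != "dom0001"]
  expect_lt(abs(mean(base_cells) - 40), 4)
  expect_equal(sim$truth, enr)

  sim2 <- simulate_domain_tables(n_species = 3, n_domains = 30, totals = 5000,
                                 base_mean = 40, enrichments = enr, seed = 14)
  expect_equal(sim2$table$annotations, sim$table$annotations)

  expect_error(simulate_domain_tables(totals = 100, base_mean = 60,
                                      enrichments = enr, seed = 1),
               "exceeds")
})

test_that("orthogroup simulation plants occupancy patterns exactly", {
  planted <- c(`A&B&C&D` = 40, A = 21)
  sim <- simulate_orthogroups(planted, seed = 3)
  occ <- occupancy_summary(sim$table)
  got <- stats::setNames(occ$patterns$n_ogs, occ$patterns$pattern)
  expect_equal(got[names(planted)], planted)

  empty <- simulate_orthogroups(stats::setNames(integer(), character()),
                                unassigned_per_species = c(A = 2), seed = 1)
  expect_equal(nrow(empty$table$genes), 0)
  expect_equal(nrow(empty$table$unassigned), 2)

  s1 <- simulate_orthogroups(planted, seed = 9)
  s2 <- simulate_orthogroups(planted, seed = 9)
  expect_equal(s1$table$genes, s2$table$genes)
})

test_that("expression simulation plants a silent fraction below the filter", {
  genes <- sprintf("g%03d", 1:400)
  sim <- simulate_expression(genes, silent_fraction = 1, seed = 2)
  expect_true(all(sim$table$pooled_count < 5))

  sim0 <- simulate_expression(genes, silent_fraction = 0, active_mean = 100,
                              seed = 2)
  expect_length(sim0$truth, 0)
  expect_true(all(sim0$table$pooled_count >= 5))

  sim_mix <- simulate_expression(genes, silent_fraction = 0.25, seed = 4)
  expect_length(sim_mix$truth, 100)
  expect_true(all(sim_mix$table$pooled_count[match(sim_mix$truth,
                                                   sim_mix$table$gene_id)] < 5))

  expect_identical(simulate_expression(genes, 0.25, seed = 4)$table,
                   sim_mix$table)
})

test_that("generators use independent substreams of the global seed", {
  g <- simulate_genome(1, 1000, seed = 42)
  o <- simulate_orthogroups(c(A = 3), seed = 42)
  g2 <- simulate_genome(1, 1000, seed = 42)
  # simulating something else in between does not perturb the genome stream
  expect_identical(as.character(g), as.character(g2))
  # and the caller's RNG state is untouched
  set.seed(1)
  before <- .Random.seed
  invisible(simulate_genome(1, 500, seed = 5))
  expect_identical(.Random.seed, before)
})
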