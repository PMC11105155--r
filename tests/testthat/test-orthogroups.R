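test_that("occupancy summary partitions orthogroups and recovers planted patterns", {
  planted <- c(`A&B&C&D` = 40, A = 21, `A&B` = 11, `B&C` = 3)
  sim <- simulate_orthogroups(planted, unassigned_per_species = c(A = 5),
                              seed = 4)
  occ <- occupancy_summary(sim$table)
  expect_equal(occ$total_ogs, sum(planted))
  got <- stats::setNames(occ$patterns$n_ogs, occ$patterns$pattern)
  expect_equal(got[names(planted)], planted)
  expect_equal(sum(occ$patterns$n_ogs), occ$total_ogs)
  expect_equal(sum(occ$patterns$pct_ogs), 100)

  expect_equal(occ$patterns$pct_ogs[occ$patterns$pattern == "A&B&C&D"],
               100 * 40 / 75)
  a <- occ$per_species[occ$per_species$species == "A", ]
  expect_equal(a$pct_ogs_with_gene, 100 * (40 + 21 + 11) / 75)
  expect_equal(a$pct_species_specific_ogs, 100 * 21 / 75)

  bad <- sim$table
  bad$species <- c("A", "B")  # drop C and D from the declared species
  expect_error(occupancy_summary(bad, species = c("A", "B")), "missing")
})

test_that("gene accounting partitions each species' genes", {
  genes <- tibble::tibble(
    og_id = c(rep("OG1", 2), rep("OG2", 2), "OG3"),
    species = c("A", "B", "A", "A", "B"),
    gene_id = c("a1", "b1", "a2", "a3", "b2")
  )
  una <- tibble::tibble(species = c("A", "A"), gene_id = c("a4", "a5"))
  x <- orthogroup_table(genes, una)
  acc <- gene_accounting(x)
  a <- acc[acc$species == "A", ]
  # A: 5 genes total; 3 assigned (a1 in shared OG1, a2+a3 in A-only OG2)
  expect_equal(a$n_genes, 5L)
  expect_equal(a$pct_assigned, 60)
  expect_equal(a$pct_not_assigned, 40)
  expect_equal(a$pct_in_species_specific_og, 40)
  expect_equal(a$pct_potentially_specific, 80)
  expect_equal(a$pct_assigned + a$pct_not_assigned, 100)

  b <- acc[acc$species == "B", ]
  expect_equal(b$pct_potentially_specific,
               b$pct_not_assigned + b$pct_in_species_specific_og)

  # all genes in multi-species OGs: potentially specific = not assigned
  x2 <- orthogroup_table(genes[genes$og_id == "OG1", ], una)
  acc2 <- gene_accounting(x2)
  expect_equal(acc2$pct_potentially_specific, acc2$pct_not_assigned)

  # nothing assigned
  x3 <- orthogroup_table(genes[0, ], una, species = "A")
  acc3 <- gene_accounting(x3)
  expect_equal(acc3$pct_assigned, 0)
  expect_equal(acc3$pct_not_assigned, 100)
})

test_that("expression filter keeps genes with pooled counts >= 5", {
  genes <- tibble::tibble(og_id = "OG1", species = "A",
                          gene_id = c("g1", "g2", "g3"))
  una <- tibble::tibble(species = "A", gene_id = c("u1", "u2", "u3"))
  x <- orthogroup_table(genes, una)
  expr <- tibble::tibble(gene_id = c("g1", "g2", "g3", "u1", "u2"),
                         pooled_count = c(10, 4, 5, 10, 4))

  ps <- suppressMessages(potentially_specific_genes(x, "A", expr))
  # OG1 is A-only, so assigned genes count as potentially specific too
  expect_setequal(ps$genes, c("g1", "g2", "g3", "u1", "u2", "u3"))
  # u3 missing from expr -> count 0 -> filtered; exactly 5 retained
  expect_message(
    ps2 <- potentially_specific_genes(x, "A", expr),
    "absent from the expression table")
  expect_setequal(ps2$expressed, c("g1", "g3", "u1"))

  empty_expr <- tibble::tibble(gene_id = character(), pooled_count = double())
  expect_warning(
    suppressMessages(ps3 <- potentially_specific_genes(x, "A", empty_expr)),
    "no potentially")
  expect_length(ps3$expressed, 0)
})

test_that("set enrichment handles extreme, null and frozen-oracle tables", {
  # target = exactly the genes with the domain, background twice the size
  target <- sprintf("t%d", 1:10)
  bg <- c(target, sprintf("b%d", 1:10))
  ann <- tibble::tibble(gene_id = target, domain_id = "d")
  res <- set_enrichment(target, bg, ann)
  d_row <- res[res$domain_id == "d", ]
  expect_equal(d_row$odds_ratio, Inf)
  expect_equal(d_row$p, brute_fisher_p(10, 0, 0, 10))
  # unannotated background genes surface as the no_Pfam pseudo-domain
  expect_true("no_Pfam" %in% res$domain_id)

  # domain equally frequent in target and complement: odds ratio 1
  ann2 <- tibble::tibble(gene_id = c(target[1:5], sprintf("b%d", 1:5)),
                         domain_id = "e")
  res2 <- set_enrichment(target, bg, ann2)
  expect_equal(res2$odds_ratio[res2$domain_id == "e"], 1)

  # frozen oracle: 8-of-10 target vs 2-of-10 rest has p ~ 0.023
  ann3 <- tibble::tibble(gene_id = c(target[1:8], sprintf("b%d", 1:2)),
                         domain_id = "f")
  res3 <- set_enrichment(target, bg, ann3)
  expect_equal(res3$p[res3$domain_id == "f"], 0.0230141, tolerance = 1e-5)

  expect_error(set_enrichment(c("zzz"), bg, ann), "subset")

  # BH option adjusts before thresholding
  res4 <- set_enrichment(target, bg, ann3, alpha = 0.05, fdr = TRUE)
  expect_true("p_adjusted" %in% names(res4))
  expect_equal(res4$p_adjusted, stats::p.adjust(res4$p, "BH"))
})

test_that("set enrichment controls type-I error on null simulations", {
  set.seed(55)
  bg <- sprintf("g%d", 1:1000)
  target <- sample(bg, 200)
  n_dom <- 500
  ann <- dplyr::bind_rows(lapply(seq_len(n_dom), function(d) {
    tibble::tibble(gene_id = bg[stats::runif(1000) < 0.1],
                   domain_id = sprintf("d%03d", d))
  }))
  res <- set_enrichment(target, bg, ann, alpha = 0.001)
  flagged <- sum(res$significant[res$domain_id != "no_Pfam"])
  expect_lte(flagged / n_dom, 0.003)
})

test_that("dataset summary excludes giant assemblies from the medians only", {
  size <- c(30, 37.1, 45, 700, 1030)
  genes <- c(9000, 11843, 13000, 15000, 39703)
  s <- dataset_summary(size, genes)
  expect_equal(s$median_genome_size_mb, 37.1)
  expect_equal(s$median_n_genes, 11843)
  expect_equal(s$mean_genome_size_mb, mean(size))
  expect_equal(s$n_genomes, 5)
})
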