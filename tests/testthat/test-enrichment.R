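test_that("count matrix counts distinct domain-bearing proteins", {
  ann <- tibble::tibble(
    species = c("A", "A", "A", "A", "B"),
    gene_id = c("g1", "g1", "g1", "g2", "h1"),
    domain_id = c("Lipase_3", "Lipase_3", "Lipase_3", "Lipase_3", "M16"),
    domain_type = c("PFAM", "PFAM", "PFAM", "PFAM", "MEROPS"),
    secreted = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  m <- build_count_matrix(domain_annotation(ann, c(A = 10, B = 10)))
  # g1 carries three copies of Lipase_3 but contributes 1
  expect_equal(m$counts["A", "Lipase_3"], 2L)
  expect_equal(m$counts["B", "Lipase_3"], 0L)
  expect_equal(m$secreted_counts["A", "Lipase_3"], 1L)
  expect_equal(unname(m$domain_type["M16"]), "MEROPS")
})

test_that("two-sided Fisher p matches enumeration, transposition and fisher.test", {
  res <- fisher_two_sided(0, 5, 5, 0)
  expect_equal(res$p, 2 / 252)
  expect_equal(res$odds_ratio, 0)

  expect_equal(fisher_two_sided(1, 1, 1, 1)$p, 1)
  expect_equal(fisher_two_sided(5, 0, 0, 5)$p, fisher_two_sided(0, 5, 5, 0)$p)
  expect_equal(fisher_two_sided(5, 0, 0, 5)$odds_ratio, Inf)
  expect_equal(fisher_two_sided(3, 6, 2, 4)$odds_ratio, 1)

  expect_error(fisher_two_sided(0, 0, 3, 4), "positive")
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")

  # enumeration oracle over a sweep of small tables
  for (n in c(6, 11, 17)) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        for (a in max(0, c1 - (n - r1)):min(r1, c1)) {
          b <- r1 - a; cc <- c1 - a; dd <- n - r1 - c1 + a
          expect_equal(fisher_two_sided(a, b, cc, dd)$p,
                       brute_fisher_p(a, b, cc, dd), tolerance = 1e-12)
        }
      }
    }
  }

  # independent route: stats::fisher.test on random tables
  set.seed(21)
  for (i in 1:100) {
    tb <- matrix(rpois(4, 7) + c(1, 0, 0, 1), 2)
    expect_equal(fisher_two_sided(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])$p,
                 stats::fisher.test(tb)$p.value, tolerance = 1e-12)
  }
})

test_that("pairwise enrichment reproduces fold-versus-median directions", {
  # printed BD-FAE counts across seven proteomes; the count-1 species is
  # 20-fold under the median
  m <- build_count_matrix(fixture_single_domain(c(1, 2, 3, 23, 25, 20, 23),
                                                domain_id = "BD-FAE"))
  pe <- pairwise_enrichment(m)
  row <- pe$summary[pe$summary$count == 1, ]
  expect_equal(row$direction, "down")
  expect_equal(row$fold, 20)
  expect_equal(row$median, 20)

  # Lipase_3-style overrepresentation: count 348 against median 66
  m2 <- build_count_matrix(fixture_single_domain(c(348, 132, 190, 66, 66, 40, 30),
                                                 domain_id = "Lipase_3"))
  pe2 <- pairwise_enrichment(m2)
  row2 <- pe2$summary[pe2$summary$count == 348, ]
  expect_equal(row2$direction, "up")
  expect_equal(row2$fold, 348 / 66)
  expect_equal(round(row2$fold, 1), 5.3)

  # equal counts: fold 1, at median, no significant pairs
  m3 <- build_count_matrix(fixture_single_domain(rep(5, 4)))
  pe3 <- pairwise_enrichment(m3)
  expect_true(all(pe3$summary$direction == "at_median"))
  expect_true(all(pe3$summary$fold == 1))
  expect_true(all(pe3$summary$n_significant_pairs == 0))
})

test_that("pairwise enrichment applies the per-domain Bonferroni family", {
  m <- build_count_matrix(fixture_single_domain(c(40, 5, 5, 5), total = 1000))
  pe <- pairwise_enrichment(m, alpha = 0.01)
  n_pairs <- choose(4, 2)
  expect_equal(pe$pairwise$p_adjusted,
               pmin(1, pe$pairwise$p_raw * n_pairs))
  top <- pe$summary[pe$summary$count == 40, ]
  expect_equal(top$n_significant_pairs,
               sum(pe$pairwise$p_adjusted[pe$pairwise$species_1 == "sp1" |
                                          pe$pairwise$species_2 == "sp1"] <= 0.01))

  # global family multiplies by pairs x domains
  sim <- simulate_domain_tables(n_species = 3, n_domains = 4, totals = 500,
                                base_mean = 8, seed = 2)
  mg <- build_count_matrix(sim$table)
  pg <- pairwise_enrichment(mg, global_bonferroni = TRUE)
  n_dom <- length(unique(pg$pairwise$domain_id))
  expect_equal(pg$pairwise$p_adjusted,
               pmin(1, pg$pairwise$p_raw * choose(3, 2) * n_dom))
})

test_that("domains present in fewer than two genomes are excluded", {
  ann <- tibble::tibble(
    species = c("A", "A", "B"),
    gene_id = c("g1", "g2", "h1"),
    domain_id = c("solo", "shared", "shared"),
    domain_type = "PFAM", secreted = FALSE
  )
  m <- build_count_matrix(domain_annotation(ann, c(A = 50, B = 50)))
  pe <- pairwise_enrichment(m)
  expect_false("solo" %in% pe$summary$domain_id)
  expect_true("shared" %in% pe$summary$domain_id)
})

test_that("2x2 chi-squared uses no continuity correction", {
  res <- chisq_2x2(17, 3, 45, 60)
  expect_equal(res$p, 0.00055, tolerance = 0.02)
  expect_equal(res$chi2, 125 * (17 * 60 - 3 * 45)^2 / (20 * 105 * 62 * 63))

  expect_equal(chisq_2x2(5, 5, 5, 5)$chi2, 0)
  expect_equal(chisq_2x2(5, 5, 5, 5)$p, 1)
  expect_equal(chisq_2x2(10, 0, 0, 10)$chi2, 20)
  expect_error(chisq_2x2(0, 0, 5, 5), "positive")
})

test_that("presence sets partition the domains", {
  ann <- tibble::tibble(
    species = c("A", "A", "B", "B"),
    gene_id = c("g1", "g2", "h1", "h2"),
    domain_id = c("x", "y", "y", "z"),
    domain_type = "PFAM", secreted = FALSE
  )
  m <- build_count_matrix(domain_annotation(ann, c(A = 10, B = 10)))
  ps <- presence_sets(m)
  expect_equal(ps$n_domains[ps$pattern == "A"], 1L)
  expect_equal(ps$n_domains[ps$pattern == "B"], 1L)
  expect_equal(ps$n_domains[ps$pattern == "A&B"], 1L)
  expect_equal(sum(ps$n_domains), ncol(m$counts))

  sim <- simulate_domain_tables(n_species = 5, n_domains = 40, totals = 300,
                                base_mean = 2, seed = 9)
  ms <- build_count_matrix(sim$table)
  expect_equal(sum(presence_sets(ms)$n_domains), ncol(ms$counts))
})
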