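#!/usr/bin/env Rscript
# Step 1: generate every synthetic input for the downstream analyses, with
# planted ground truth serialized next to each output. All later steps read
# only from results/sim/.

suppressPackageStartupMessages({
  library(entomocomp)
  library(tibble)
})

seed <- 20240520
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating a 600 kb assembly and planting RIP at rate 0.3 ...")
genome <- simulate_genome(n_contigs = 1, lengths = 6e5, gc = 0.5, seed = seed)
planted_starts <- seq(0, 595000, by = 5000)
windows <- data.frame(contig = "contig_1", start = planted_starts,
                      end = planted_starts + 1000)
mut <- plant_rip(genome, windows, rate = 0.3, seed = seed)
write_fasta(mut$genome, file.path(out, "genome_ripped.fa"))
write_fasta(genome, file.path(out, "genome_clean.fa"))
jsonlite::write_json(mut$truth, file.path(out, "rip_truth.json"))

message("simulating domain tables for 4 proteomes, 200 domains, 20 planted 5x enrichments ...")
enr <- tibble(species = "sp01", domain_id = sprintf("dom%04d", 1:20), fold = 5)
dom <- simulate_domain_tables(n_species = 4, n_domains = 200, totals = 10000,
                              base_mean = 50, enrichments = enr, seed = seed)
write_domain_table(dom$table, file.path(out, "domains.tsv"),
                   file.path(out, "proteome_totals.tsv"))
jsonlite::write_json(dom$truth, file.path(out, "enrichment_truth.json"))

message("simulating orthogroups with the study's occupancy proportions (1/10 scale) ...")
og_counts <- c(`EMA&EMU&NTH&ZRA` = 688, `EMA&EMU` = 185, `EMA&EMU&ZRA` = 128,
               `EMA&EMU&NTH` = 41, EMU = 359, ZRA = 118, EMA = 86, NTH = 39,
               `EMA&ZRA` = 15, `NTH&ZRA` = 12, `EMU&ZRA` = 14, `EMA&NTH` = 9,
               `EMU&NTH` = 8, `EMA&NTH&ZRA` = 5, `EMU&NTH&ZRA` = 4)
ogs <- simulate_orthogroups(og_counts, genes_per_og_range = c(1, 3),
                            unassigned_per_species = c(EMU = 300, EMA = 80,
                                                       ZRA = 70, NTH = 40),
                            seed = seed)
write_orthogroups(ogs$table, file.path(out, "orthogroups.tsv"),
                  file.path(out, "orthogroups_unassigned.tsv"))
jsonlite::write_json(as.list(ogs$truth), file.path(out, "og_truth.json"),
                     auto_unbox = TRUE)

message("simulating pooled expression for EMU's potentially specific genes (30% silent) ...")
ps <- potentially_specific_genes(ogs$table, "EMU")
expr <- simulate_expression(ps$genes, silent_fraction = 0.3, seed = seed)
write_expression(expr$table, file.path(out, "expression.tsv"))
jsonlite::write_json(expr$truth, file.path(out, "silent_truth.json"))

message("simulating repeat divergence records (Ty3 39.1%, TcMar 12%, L1 1%) ...")
reps <- simulate_repeats(c(`LTR/Ty3` = 0.391, `DNA/TcMar` = 0.12,
                           `LINE/L1` = 0.01, `Unknown` = 0.002),
                         genome_size = 5e5, n_elements_per_class = 200,
                         divergence_range = list(`LTR/Ty3` = c(5, 50),
                                                 `DNA/TcMar` = c(0, 25),
                                                 `LINE/L1` = c(20, 45),
                                                 `Unknown` = c(0, 50)),
                         seed = seed)
write_repeat_divergence(reps$records, file.path(out, "repeats.tsv"))
jsonlite::write_json(as.list(reps$truth), file.path(out, "repeat_truth.json"),
                     auto_unbox = TRUE)

message("done: inputs and truth written under ", out)
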