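# Post-clustering orthogroup statistics: occupancy patterns, core and
# species-specific sets, per-species gene accounting, pooled-expression
# filtering of potentially species-specific genes, and Pfam set enrichment.

#' @noRd
og_patterns <- function(x, species, sep = "&") {
  pres <- unique(x$genes[c("og_id", "species")])
  pres$species <- factor(pres$species, levels = species)
  split_sp <- split(pres$species, pres$og_id)
  vapply(split_sp, function(s) {
    paste(species[sort(unique(as.integer(s)))], collapse = sep)
  }, character(1))
}

#' Orthogroup occupancy summary
#'
#' Assigns every orthogroup to exactly one species-subset pattern (the set of
#' species contributing at least one gene), so pattern counts partition the
#' orthogroups. Also reports, per species, the percentage of orthogroups
#' containing at least one of its genes and the percentage populated by that
#' species alone, both against the total number of orthogroups.
#'
#' @param x An [orthogroup_table].
#' @param species Species order for rendering patterns; must cover every
#'   species present in `x`.
#' @param sep Pattern separator.
#' @return List of class `occupancy_summary` with tibbles `patterns`
#'   (`pattern`, `n_species`, `n_ogs`, `pct_ogs`) and `per_species`
#'   (`species`, `pct_ogs_with_gene`, `pct_species_specific_ogs`), plus
#'   `total_ogs`.
#' @export
occupancy_summary <- function(x, species = x$species, sep = "&") {
  stopifnot(inherits(x, "orthogroup_table"))
  extra <- setdiff(unique(x$genes$species), species)
  if (length(extra)) {
    stop("species in table missing from `species`: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  pat <- og_patterns(x, species, sep)
  total <- length(pat)
  tb <- table(pat)
  patterns <- tibble::tibble(
    pattern = names(tb),
    n_species = lengths(strsplit(names(tb), sep, fixed = TRUE)),
    n_ogs = as.integer(tb),
    pct_ogs = 100 * as.integer(tb) / total
  )
  pattern_members <- strsplit(names(tb), sep, fixed = TRUE)
  per_species <- tibble::tibble(
    species = species,
    pct_ogs_with_gene = vapply(species, function(s) {
      has <- vapply(pattern_members, function(p) s %in% p, logical(1))
      100 * sum(as.integer(tb)[has]) / total
    }, double(1), USE.NAMES = FALSE),
    pct_species_specific_ogs = vapply(species, function(s) {
      100 * sum(as.integer(tb)[names(tb) == s]) / total
    }, double(1), USE.NAMES = FALSE)
  )
  structure(list(patterns = patterns, per_species = per_species,
                 total_ogs = total),
            class = "occupancy_summary")
}

#' Per-species gene accounting
#'
#' Partitions each species' gene universe (assigned plus unassigned) into
#' assigned / not-assigned, with assigned genes further split by whether
#' their orthogroup is species-specific. "Potentially species-specific" is
#' the sum of not-assigned genes and genes in species-specific orthogroups.
#' If `expr` is given, the additional column
#' `pct_potentially_specific_expressed` keeps only potentially specific genes
#' whose pooled count is at least `min_count` (genes missing from `expr`
#' count as zero).
#'
#' @param x An [orthogroup_table].
#' @param species Species to report (default: all in the table).
#' @param expr Optional expression tibble (`gene_id`, `pooled_count`).
#' @param min_count Pooled-count threshold; genes with counts strictly below
#'   it are treated as silent (default 5).
#' @return Tibble with one row per species: `n_genes`, `pct_assigned`,
#'   `pct_not_assigned`, `pct_in_species_specific_og`,
#'   `pct_potentially_specific` and (with `expr`)
#'   `pct_potentially_specific_expressed`.
#' @export
gene_accounting <- function(x, species = x$species, expr = NULL, min_count = 5) {
  stopifnot(inherits(x, "orthogroup_table"))
  pat <- og_patterns(x, species)
  rows <- lapply(species, function(s) {
    assigned <- x$genes$gene_id[x$genes$species == s]
    unassigned <- x$unassigned$gene_id[x$unassigned$species == s]
    n <- length(assigned) + length(unassigned)
    sp_ogs <- names(pat)[pat == s]
    in_sp <- x$genes$gene_id[x$genes$species == s & x$genes$og_id %in% sp_ogs]
    pot <- c(unassigned, in_sp)
    row <- tibble::tibble(
      species = s,
      n_genes = n,
      pct_assigned = if (n) 100 * length(assigned) / n else 0,
      pct_not_assigned = if (n) 100 * length(unassigned) / n else 100,
      pct_in_species_specific_og = if (n) 100 * length(in_sp) / n else 0,
      pct_potentially_specific = if (n) 100 * length(pot) / n else 100
    )
    if (!is.null(expr)) {
      counts <- expr$pooled_count[match(pot, expr$gene_id)]
      counts[is.na(counts)] <- 0
      row$pct_potentially_specific_expressed <-
        if (n) 100 * sum(counts >= min_count) / n else 0
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Potentially species-specific genes, with pooled-expression filter
#'
#' The potentially species-specific set is the union of the species'
#' unassigned genes and its genes in orthogroups populated by that species
#' alone. Genes with a pooled count strictly below `min_count` are filtered
#' out of the expressed set ("fewer than five estimated counts" with the
#' default); genes absent from the expression table count as zero (absence
#' from quantification output is no evidence of expression) and are logged.
#'
#' @param x An [orthogroup_table].
#' @param sp Species of interest.
#' @param expr Optional expression tibble (`gene_id`, `pooled_count`). If
#'   `NULL`, the filtered set equals the full set.
#' @param min_count Threshold (kept iff pooled count >= `min_count`).
#' @return List with character vectors `genes` and `expressed`.
#' @export
potentially_specific_genes <- function(x, sp, expr = NULL, min_count = 5) {
  stopifnot(inherits(x, "orthogroup_table"), sp %in% x$species)
  pat <- og_patterns(x, x$species)
  sp_ogs <- names(pat)[pat == sp]
  genes <- unique(c(
    x$unassigned$gene_id[x$unassigned$species == sp],
    x$genes$gene_id[x$genes$species == sp & x$genes$og_id %in% sp_ogs]
  ))
  if (is.null(expr)) {
    return(list(genes = genes, expressed = genes))
  }
  counts <- expr$pooled_count[match(genes, expr$gene_id)]
  n_missing <- sum(is.na(counts))
  if (n_missing > 0) {
    message(n_missing, " gene(s) absent from the expression table; treated as count 0")
  }
  counts[is.na(counts)] <- 0
  expressed <- genes[counts >= min_count]
  if (!length(expressed) && length(genes)) {
    warning("no potentially species-specific gene passed the expression filter",
            call. = FALSE)
  }
  list(genes = genes, expressed = expressed)
}

#' Domain set enrichment of a gene subset
#'
#' For every domain annotated on the background (plus the pseudo-domain
#' `no_Pfam` for genes with no annotation, reported as a category in its own
#' right), tests the 2x2 table of target membership against domain presence
#' with a two-sided Fisher exact test. The odds ratio is the sample odds
#' ratio of the table. By default significance is a raw p threshold
#' (`p <= alpha`); `fdr = TRUE` applies Benjamini-Hochberg first.
#'
#' @param target_genes Character vector, a subset of `background_genes`.
#' @param background_genes Character vector of all genes considered.
#' @param annotations Either a data frame with columns `gene_id`, `domain_id`
#'   or a named list mapping gene id to a character vector of domains.
#' @param alpha Significance threshold (default 0.001).
#' @param fdr Apply Benjamini-Hochberg adjustment before thresholding.
#' @return Tibble `domain_id`, `n_target`, `n_background`, `odds_ratio`, `p`,
#'   (`p_adjusted` when `fdr`), `significant`.
#' @export
set_enrichment <- function(target_genes, background_genes, annotations,
                           alpha = 0.001, fdr = FALSE) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  if (length(setdiff(target_genes, background_genes))) {
    stop("target genes must be a subset of the background", call. = FALSE)
  }
  if (is.data.frame(annotations)) {
    ann <- tibble::as_tibble(annotations)[c("gene_id", "domain_id")]
  } else {
    ann <- tibble::tibble(
      gene_id = rep(names(annotations), lengths(annotations)),
      domain_id = unlist(annotations, use.names = FALSE) %||% character()
    )
  }
  ann <- unique(ann[ann$gene_id %in% background_genes, ])
  no_ann <- setdiff(background_genes, unique(ann$gene_id))
  ann <- dplyr::bind_rows(ann, tibble::tibble(gene_id = no_ann,
                                              domain_id = "no_Pfam"))
  n_t <- length(target_genes)
  n_b <- length(background_genes)
  by_dom <- split(ann$gene_id, ann$domain_id)
  rows <- lapply(names(by_dom), function(d) {
    genes_d <- by_dom[[d]]
    a <- length(intersect(genes_d, target_genes))
    b <- n_t - a
    cc <- length(genes_d) - a
    dd <- (n_b - n_t) - cc
    ft <- fisher_two_sided(a, b, cc, dd)
    tibble::tibble(domain_id = d, n_target = a, n_background = length(genes_d),
                   odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out <- dplyr::bind_rows(rows)
  if (fdr) {
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adjusted <= alpha
  } else {
    out$significant <- out$p <= alpha
  }
  out
}

#' Summary statistics over a compiled genome-size / gene-count dataset
#'
#' Medians are taken after excluding assemblies larger than `size_cutoff_mb`
#' (giant TE-inflated genomes would otherwise dominate); the mean genome size
#' is over all genomes.
#'
#' @param genome_size_mb Numeric vector of assembly sizes in Mb.
#' @param n_genes Numeric vector of predicted gene counts (same length).
#' @param size_cutoff_mb Exclusion threshold for the medians (default 500).
#' @return List: `n_genomes`, `median_genome_size_mb`, `median_n_genes`
#'   (both over genomes <= cutoff) and `mean_genome_size_mb` (all genomes).
#' @export
dataset_summary <- function(genome_size_mb, n_genes, size_cutoff_mb = 500) {
  stopifnot(length(genome_size_mb) == length(n_genes))
  keep <- genome_size_mb <= size_cutoff_mb
  list(
    n_genomes = length(genome_size_mb),
    median_genome_size_mb = stats::median(genome_size_mb[keep]),
    median_n_genes = stats::median(n_genes[keep]),
    mean_genome_size_mb = mean(genome_size_mb)
  )
}
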