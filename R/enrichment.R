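# Cross-species protein-domain enrichment: species-by-domain count matrices,
# pairwise Fisher exact tests with Bonferroni correction, fold-versus-median
# summaries, domain presence-set intersections, and the secreted-fraction
# chi-squared comparison.

#' Build a species-by-domain count matrix
#'
#' A protein carrying k copies of a domain contributes 1 to the count
#' (accession-level counting: distinct proteins, not domain occurrences).
#' Secreted counts are the same restricted to proteins flagged secreted.
#'
#' @param x A [domain_annotation] object.
#' @return An object of class `domain_count_matrix`: list with `counts` and
#'   `secreted_counts` (integer matrices, species x domain), `totals` (named
#'   vector of proteome sizes) and `domain_type` (named by domain).
#' @export
build_count_matrix <- function(x) {
  stopifnot(inherits(x, "domain_annotation"))
  ann <- unique(x$annotations[c("species", "gene_id", "domain_id",
                                "domain_type", "secreted")])
  species <- names(x$totals)
  domains <- sort(unique(ann$domain_id))
  sp_f <- factor(ann$species, levels = species)
  dom_f <- factor(ann$domain_id, levels = domains)
  counts <- as.matrix(table(sp_f, dom_f))
  sec <- as.matrix(table(sp_f[ann$secreted], factor(ann$domain_id[ann$secreted],
                                                    levels = domains)))
  sec_full <- matrix(0L, nrow = length(species), ncol = length(domains),
                     dimnames = dimnames(counts))
  sec_full[rownames(sec), ] <- sec
  dtype <- vapply(split(ann$domain_type, dom_f), function(v) v[1], character(1))
  if (any(counts > x$totals[rownames(counts)])) {
    stop("domain count exceeds proteome total", call. = FALSE)
  }
  structure(list(counts = counts, secreted_counts = sec_full,
                 totals = x$totals[species], domain_type = dtype),
            class = "domain_count_matrix")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p for the table `[[a, b], [c, d]]` by summation of
#' hypergeometric probabilities no larger than that of the observed table
#' (the classical "probability <= observed" rule, with the same relative
#' tolerance `1 + 1e-7` as [stats::fisher.test()]). The odds ratio is the
#' sample odds ratio `ad/bc`, reported as `Inf` when `bc = 0` (and `NaN` when
#' both products are zero), not the conditional MLE.
#'
#' @param a,b,c,d Non-negative integer cell counts; both row sums and both
#'   column sums must be positive.
#' @return List with elements `p` and `odds_ratio`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("all row and column sums must be positive", call. = FALSE)
  }
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  k <- lo:hi
  probs <- stats::dhyper(k, r1, n - r1, c1)
  d0 <- stats::dhyper(a, r1, n - r1, c1)
  p <- min(1, sum(probs[probs <= d0 * (1 + 1e-7)]))
  odds <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(p = p, odds_ratio = odds)
}

#' Pairwise Fisher enrichment of domain counts across species
#'
#' Domains present (count > 0) in fewer than two genomes are excluded. For
#' each retained domain, every unordered species pair is tested with a
#' two-sided Fisher exact test on
#' `[[count_i, total_i - count_i], [count_j, total_j - count_j]]` (whole
#' annotated proteomes as denominators, so genes without any domain still
#' count against the background). Raw p values are Bonferroni-corrected by
#' the number of pairs tested per domain (or by pairs x domains when
#' `global_bonferroni = TRUE`) and capped at 1. Per species, the fold versus
#' the across-species median (zeros included) is `count/median` when above
#' the median and `median/count` when below (`Inf` when the count is 0);
#' ties with the median give direction `at_median` and fold 1.
#'
#' @param m A `domain_count_matrix` from [build_count_matrix()].
#' @param alpha Significance threshold on the adjusted p (default 0.01).
#' @param global_bonferroni Multiply by pairs x domains instead of pairs.
#' @return List of class `pairwise_enrichment` with tibbles `summary`
#'   (domain_type, domain_id, species, count, median, fold, direction,
#'   n_significant_pairs, min_adjusted_p) and `pairwise` (domain_id,
#'   species_1, species_2, p_raw, p_adjusted).
#' @export
pairwise_enrichment <- function(m, alpha = 0.01, global_bonferroni = FALSE) {
  stopifnot(inherits(m, "domain_count_matrix"))
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1)) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  species <- rownames(m$counts)
  if (length(species) < 2) stop("need at least two species", call. = FALSE)
  keep <- colSums(m$counts > 0) >= 2
  domains <- colnames(m$counts)[keep]
  pairs <- utils::combn(species, 2)
  n_pairs <- ncol(pairs)
  bonf <- if (global_bonferroni) n_pairs * length(domains) else n_pairs
  pw <- vector("list", length(domains))
  sm <- vector("list", length(domains))
  for (di in seq_along(domains)) {
    d <- domains[di]
    cnt <- m$counts[, d]
    p_raw <- vapply(seq_len(n_pairs), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      fisher_two_sided(cnt[i], m$totals[i] - cnt[i],
                       cnt[j], m$totals[j] - cnt[j])$p
    }, double(1))
    p_adj <- pmin(1, p_raw * bonf)
    pw[[di]] <- tibble::tibble(domain_id = d, species_1 = pairs[1, ],
                               species_2 = pairs[2, ], p_raw = p_raw,
                               p_adjusted = p_adj)
    med <- stats::median(cnt)
    fold <- ifelse(cnt == med, 1,
                   ifelse(cnt > med,
                          ifelse(med == 0, Inf, cnt / med),
                          ifelse(cnt == 0, Inf, med / cnt)))
    direction <- ifelse(cnt == med, "at_median", ifelse(cnt > med, "up", "down"))
    involved <- function(s) pairs[1, ] == s | pairs[2, ] == s
    n_sig <- vapply(species, function(s) sum(p_adj[involved(s)] <= alpha),
                    integer(1))
    min_adj <- vapply(species, function(s) min(p_adj[involved(s)]), double(1))
    sm[[di]] <- tibble::tibble(domain_type = unname(m$domain_type[d]),
                               domain_id = d, species = species,
                               count = unname(cnt), median = med,
                               fold = unname(fold),
                               direction = unname(direction),
                               n_significant_pairs = unname(n_sig),
                               min_adjusted_p = unname(min_adj))
  }
  structure(list(summary = dplyr::bind_rows(sm),
                 pairwise = dplyr::bind_rows(pw),
                 alpha = alpha),
            class = "pairwise_enrichment")
}

#' Pearson chi-squared test on a 2x2 table, without continuity correction
#'
#' @param a,b,c,d Cell counts of the table `[[a, b], [c, d]]`; all row and
#'   column sums must be positive.
#' @return List with elements `chi2` (the statistic, df = 1) and `p`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("cells must be non-negative", call. = FALSE)
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("all row and column sums must be positive", call. = FALSE)
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Presence-set intersections of domains across species
#'
#' Assigns every domain to exactly one species subset: the exact set of
#' species in which it is present (count > 0). Subset counts therefore sum to
#' the number of domains (the cells of an UpSet plot).
#'
#' @param m A `domain_count_matrix`.
#' @param sep Separator used to render subset patterns (default `"&"`).
#' @return Tibble with columns `pattern` (species names joined by `sep`, in
#'   matrix row order), `n_species` and `n_domains`.
#' @export
presence_sets <- function(m, sep = "&") {
  stopifnot(inherits(m, "domain_count_matrix"))
  if (ncol(m$counts) == 0) {
    return(tibble::tibble(pattern = character(), n_species = integer(),
                          n_domains = integer()))
  }
  species <- rownames(m$counts)
  pres <- m$counts > 0
  patterns <- apply(pres, 2, function(col) paste(species[col], collapse = sep))
  tb <- table(patterns)
  out <- tibble::tibble(pattern = names(tb),
                        n_species = lengths(strsplit(names(tb), sep, fixed = TRUE)),
                        n_domains = as.integer(tb))
  out[out$pattern != "", ]
}
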