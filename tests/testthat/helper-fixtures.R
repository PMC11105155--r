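# Shared fixture builders; everything is generated in code.

# A tiny domain annotation table: explicit per-species counts for one domain,
# equal proteome totals.
fixture_single_domain <- function(counts, domain_id = "dom1", total = 10000,
                                  domain_type = "PFAM") {
  species <- sprintf("sp%d", seq_along(counts))
  rows <- lapply(seq_along(counts), function(i) {
    if (counts[i] == 0) return(NULL)
    tibble::tibble(species = species[i],
                   gene_id = sprintf("%s_g%d", species[i], seq_len(counts[i])),
                   domain_id = domain_id, domain_type = domain_type,
                   secreted = FALSE)
  })
  domain_annotation(dplyr::bind_rows(rows),
                    stats::setNames(rep(total, length(counts)), species))
}

# Brute-force two-sided Fisher p by direct hypergeometric enumeration with
# binomial coefficients (independent of dhyper and of fisher_two_sided).
brute_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1)
  }, double(1))
  d0 <- choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  min(1, sum(probs[probs <= d0 * (1 + 1e-7)]))
}

# Brute-force dinucleotide tally by walking a string position by position.
brute_dinuc <- function(s) {
  out <- stats::setNames(integer(16),
                         as.vector(t(outer(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T"), paste0))))
  if (nchar(s) < 2) return(out)
  for (i in 1:(nchar(s) - 1)) {
    pair <- substr(s, i, i + 1)
    if (pair %in% names(out)) out[pair] <- out[pair] + 1L
  }
  out
}

# Brute-force RIP indices from a raw sequence string.
brute_rip_indices <- function(s) {
  d <- brute_dinuc(s)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  p <- ratio(d[["TA"]], d[["AT"]])
  q <- ratio(d[["CA"]] + d[["TG"]], d[["AC"]] + d[["GT"]])
  c(product_index = p, substrate_index = q, composite_index = p - q)
}

# Independent checker for architecture rules: evaluates the rule as one
# explicit boolean expression over a dense count vector.
brute_rule <- function(profile, rule) {
  all_domains <- unique(c(names(rule$required), rule$forbidden,
                          unlist(rule$alternatives), names(profile)))
  cnt <- stats::setNames(rep(0L, length(all_domains)), all_domains)
  cnt[names(profile)] <- as.integer(profile)
  req <- TRUE
  for (d in names(rule$required)) {
    r <- rule$required[[d]]
    req <- req && if (r$mode == "exact") cnt[[d]] == r$count else cnt[[d]] >= r$count
  }
  forb <- !any(cnt[rule$forbidden] > 0)
  alt <- all(vapply(rule$alternatives, function(set) sum(cnt[set]) > 0,
                    logical(1)))
  isTRUE(req && forb && alt)
}

# Random protein profile over a fixed domain vocabulary.
random_profile <- function(vocab, max_count = 3) {
  k <- sample(0:length(vocab), 1)
  if (k == 0) return(stats::setNames(integer(), character()))
  doms <- sample(vocab, k)
  stats::setNames(sample.int(max_count, k, replace = TRUE), doms)
}

RULE_VOCAB <- c("GATA", "PAS_3", "PAS_9", "FRQ", "7tm_1", "RdRP",
                "Dicer_dimer", "PAZ", "Piwi", "Ribonuclease_3", "DEAD",
                "DNA_methylase", "GAF", "PHY")
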