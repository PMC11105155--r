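# Seeded generators for every input type, with planted ground truth, so the
# whole pipeline is testable without downloads. Every generator is a pure
# function of its parameters and seed; a single global seed fans out to
# per-component substreams, so adding a generator never perturbs existing
# streams.

BASES <- c("A", "C", "G", "T")

# Default dinucleotide odds multipliers for the background genome model.
# Unmutated (un-RIPped) fungal DNA shows strong TpA suppression (product
# index well below 1) and a mild CpA/TpG excess (substrate index above 1);
# a memoryless base model misses both and would put the composite RIP index
# of background windows at zero on average. TA and its reverse complement TA
# coincide, and CA/TG are complements, so these multipliers keep the model
# strand-symmetric.
DEFAULT_DINUC_BIAS <- c(TA = 0.75, CA = 1.15, TG = 1.15)

# First-order transition matrix whose stationary distribution hits the target
# GC exactly (fixed-point calibration of the C/G base weight).
#' @noRd
genome_transition <- function(gc, dinuc_bias = DEFAULT_DINUC_BIAS) {
  w <- matrix(1, 4, 4, dimnames = list(BASES, BASES))
  for (nm in names(dinuc_bias)) {
    w[substr(nm, 1, 1), substr(nm, 2, 2)] <- dinuc_bias[[nm]]
  }
  theta <- gc / 2
  M <- NULL
  st <- NULL
  for (it in 1:60) {
    pi0 <- c(A = (1 - 2 * theta) / 2, C = theta, G = theta,
             T = (1 - 2 * theta) / 2)
    M <- sweep(w, 2, pi0, `*`)
    M <- M / rowSums(M)
    ev <- eigen(t(M))
    st <- Re(ev$vectors[, which.max(Re(ev$values))])
    st <- st / sum(st)
    names(st) <- BASES
    gc_now <- unname(st["C"] + st["G"])
    if (abs(gc_now - gc) < 1e-12) break
    theta <- max(1e-9, min(0.5 - 1e-9, theta * sqrt(gc / gc_now)))
  }
  list(M = M, stationary = st)
}

#' @noRd
markov_chain_bases <- function(n, M, stationary) {
  cm <- t(apply(M, 1, cumsum))
  out <- integer(n)
  out[1] <- sample.int(4, 1, prob = stationary)
  if (n > 1) {
    u <- stats::runif(n)
    for (i in 2:n) {
      out[i] <- findInterval(u[i], cm[out[i - 1], ]) + 1L
    }
  }
  out
}

#' Simulate a genome with controllable GC and realistic dinucleotide skew
#'
#' Contigs are drawn from a first-order Markov base model whose stationary
#' base composition matches `gc` exactly (G and C split equally, A and T
#' likewise) and whose dinucleotide odds carry the TpA suppression and mild
#' CpA/TpG excess characteristic of unmutated fungal DNA (see
#' `dinuc_bias`; set it to `NULL` for a memoryless i.i.d. model). Output is
#' byte-identical across runs with the same arguments and seed.
#'
#' @param n_contigs Number of contigs.
#' @param lengths Contig lengths in bp (recycled to `n_contigs`); all > 0.
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param dinuc_bias Named multipliers on dinucleotide odds, or `NULL` for
#'   independent bases.
#' @return A [Biostrings::DNAStringSet] with contigs named `contig_1, ...`.
#' @export
simulate_genome <- function(n_contigs, lengths, gc = 0.5, seed = 1,
                            dinuc_bias = DEFAULT_DINUC_BIAS) {
  stopifnot(is_count(n_contigs), n_contigs >= 1)
  if (!(gc > 0 && gc < 1)) stop("gc must be in (0, 1)", call. = FALSE)
  lengths <- rep_len(as.numeric(lengths), n_contigs)
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  with_seed(fanout_seed(seed, "genome"), {
    seqs <- if (is.null(dinuc_bias)) {
      probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
      vapply(lengths, function(L) {
        paste(BASES[sample.int(4, L, replace = TRUE, prob = probs)],
              collapse = "")
      }, character(1))
    } else {
      tm <- genome_transition(gc, dinuc_bias)
      vapply(lengths, function(L) {
        paste(BASES[markov_chain_bases(L, tm$M, tm$stationary)], collapse = "")
      }, character(1))
    }
    names(seqs) <- paste0("contig_", seq_len(n_contigs))
    as_genome(seqs)
  })
}

#' Plant RIP-like mutations into chosen windows
#'
#' Within each window (0-based, half-open coordinates), every C immediately
#' followed by A is mutated to T with probability `rate`, and every G
#' immediately preceded by T is mutated to A with the same probability — the
#' two-strand CpA -> TpA signature, so the planted signal is strand-symmetric
#' like real RIP. Sites are identified on the pre-mutation sequence; bases
#' outside the windows are untouched. Windows must not overlap.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param windows Data frame with columns `contig`, `start`, `end`.
#' @param rate Per-site mutation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List: `genome` (mutated copy), `truth` (tibble of the planted
#'   windows with their `rate` and realized mutation count `n_mutated`).
#' @export
plant_rip <- function(genome, windows, rate, seed = 1) {
  if (!(is.numeric(rate) && length(rate) == 1 && rate >= 0 && rate <= 1)) {
    stop("rate must be in [0, 1]", call. = FALSE)
  }
  genome <- if (methods::is(genome, "DNAStringSet")) genome else as_genome(genome)
  windows <- tibble::as_tibble(windows)[c("contig", "start", "end")]
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(!windows$contig %in% names(genome))) {
    stop("window on unknown contig", call. = FALSE)
  }
  if (any(windows$start < 0) || any(windows$end > lens[windows$contig]) ||
      any(windows$end <= windows$start)) {
    stop("window out of contig bounds", call. = FALSE)
  }
  by_contig <- split(windows, windows$contig)
  for (w in by_contig) {
    w <- w[order(w$start), ]
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)])) {
      stop("planted windows overlap", call. = FALSE)
    }
  }
  seqs <- as.character(genome)
  truth <- windows
  truth$rate <- rate
  truth$n_mutated <- 0L
  with_seed(fanout_seed(seed, "plant_rip"), {
    for (i in seq_len(nrow(windows))) {
      ctg <- windows$contig[i]
      v <- strsplit(substr(seqs[[ctg]], windows$start[i] + 1, windows$end[i]),
                    "")[[1]]
      n <- length(v)
      if (n < 2) next
      ca_c <- which(v[-n] == "C" & v[-1] == "A")       # C of a CpA pair
      tg_g <- which(v[-n] == "T" & v[-1] == "G") + 1L  # G of a TpG pair
      mut_c <- ca_c[stats::runif(length(ca_c)) < rate]
      mut_g <- tg_g[stats::runif(length(tg_g)) < rate]
      v[mut_c] <- "T"
      v[mut_g] <- "A"
      truth$n_mutated[i] <- length(mut_c) + length(mut_g)
      substr(seqs[[ctg]], windows$start[i] + 1, windows$end[i]) <-
        paste(v, collapse = "")
    }
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genome)
  list(genome = out, truth = truth)
}

#' Simulate per-species domain annotation tables with planted enrichments
#'
#' Counts of domain-bearing proteins are Poisson with mean
#' `base_mean * fold(species, domain)` (fold 1 unless planted), capped at the
#' proteome total; genes and per-gene secreted flags are materialized to
#' match. Domain-bearing genes are sampled uniformly from each proteome, so a
#' gene can carry several domains.
#'
#' @param n_species Number of species (named `sp01, sp02, ...`).
#' @param n_domains Number of domains (named `dom0001, ...`), all `PFAM`.
#' @param totals Proteome size per species (scalar or vector of `n_species`).
#' @param base_mean Baseline Poisson mean for counts.
#' @param enrichments Optional data frame `species`, `domain_id`, `fold`
#'   (multiplicative planted enrichment, > 0).
#' @param secreted_fraction Probability a gene is flagged secreted.
#' @param seed Integer seed.
#' @return List: `table` (a [domain_annotation]) and `truth` (the enrichment
#'   tibble, possibly empty).
#' @export
simulate_domain_tables <- function(n_species = 4, n_domains = 50,
                                   totals = 10000, base_mean = 50,
                                   enrichments = NULL,
                                   secreted_fraction = 0.25, seed = 1) {
  stopifnot(is_count(n_species), n_species >= 1, is_count(n_domains),
            n_domains >= 1, base_mean > 0)
  species <- sprintf("sp%02d", seq_len(n_species))
  domains <- sprintf("dom%04d", seq_len(n_domains))
  totals <- stats::setNames(rep_len(as.integer(totals), n_species), species)
  folds <- matrix(1, n_species, n_domains, dimnames = list(species, domains))
  if (!is.null(enrichments)) {
    enrichments <- tibble::as_tibble(enrichments)[c("species", "domain_id", "fold")]
    if (any(enrichments$fold <= 0)) stop("folds must be > 0", call. = FALSE)
    folds[cbind(enrichments$species, enrichments$domain_id)] <- enrichments$fold
  }
  if (any(base_mean * folds > totals[rownames(folds)])) {
    stop("base_mean x fold exceeds the proteome total", call. = FALSE)
  }
  with_seed(fanout_seed(seed, "domains"), {
    rows <- vector("list", n_species)
    for (si in seq_len(n_species)) {
      s <- species[si]
      counts <- pmin(stats::rpois(n_domains, base_mean * folds[s, ]), totals[s])
      gene_ids <- sprintf("%s_g%05d", s, seq_len(totals[s]))
      secreted <- stats::runif(totals[s]) < secreted_fraction
      picks <- lapply(seq_len(n_domains), function(di) {
        if (counts[di] == 0) return(integer())
        sample.int(totals[s], counts[di])
      })
      idx <- unlist(picks, use.names = FALSE)
      if (length(idx)) {
        rows[[si]] <- tibble::tibble(
          species = s,
          gene_id = gene_ids[idx],
          domain_id = rep(domains, lengths(picks)),
          domain_type = "PFAM",
          secreted = secreted[idx]
        )
      }
    }
    table <- domain_annotation(dplyr::bind_rows(rows), totals)
    list(table = table,
         truth = enrichments %||% tibble::tibble(species = character(),
                                                 domain_id = character(),
                                                 fold = double()))
  })
}

#' Simulate an orthogroup table with specified occupancy patterns
#'
#' Produces exactly `pattern_counts[p]` orthogroups whose occupancy pattern
#' is `p` (species names joined by `sep`); each present species contributes a
#' uniform number of genes in `genes_per_og_range`. Per-species unassigned
#' gene lists of the requested sizes are appended.
#'
#' @param pattern_counts Named integer vector; names are non-empty species
#'   subsets like `"A&B"`.
#' @param genes_per_og_range Length-2 integer range (inclusive).
#' @param unassigned_per_species Named integer vector of unassigned gene
#'   counts (species not in any pattern may appear here too).
#' @param seed Integer seed.
#' @param sep Pattern separator (default `"&"`).
#' @return List: `table` (an [orthogroup_table]) and `truth`
#'   (`pattern_counts`).
#' @export
simulate_orthogroups <- function(pattern_counts, genes_per_og_range = c(1, 4),
                                 unassigned_per_species = integer(),
                                 seed = 1, sep = "&") {
  if (length(pattern_counts) && (is.null(names(pattern_counts)) ||
                                 any(!nzchar(names(pattern_counts))))) {
    stop("pattern_counts must be named by non-empty species subsets",
         call. = FALSE)
  }
  members <- strsplit(names(pattern_counts), sep, fixed = TRUE)
  species <- sort(unique(c(unlist(members), names(unassigned_per_species))))
  counter <- stats::setNames(rep(0L, length(species)), species)
  next_genes <- function(s, k) {
    ids <- sprintf("%s_g%05d", s, counter[[s]] + seq_len(k))
    counter[[s]] <<- counter[[s]] + k
    ids
  }
  with_seed(fanout_seed(seed, "orthogroups"), {
    rows <- list()
    og_i <- 0L
    for (pi in seq_along(pattern_counts)) {
      for (r in seq_len(pattern_counts[[pi]])) {
        og_i <- og_i + 1L
        og <- sprintf("OG%06d", og_i)
        for (s in members[[pi]]) {
          k <- sample(seq(genes_per_og_range[1], genes_per_og_range[2]), 1)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            og_id = og, species = s, gene_id = next_genes(s, k))
        }
      }
    }
    genes <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(og_id = character(), species = character(),
                     gene_id = character())
    una <- lapply(names(unassigned_per_species), function(s) {
      tibble::tibble(species = s,
                     gene_id = next_genes(s, unassigned_per_species[[s]]))
    })
    una <- if (length(una)) dplyr::bind_rows(una) else NULL
    list(table = orthogroup_table(genes, una, species = species),
         truth = pattern_counts)
  })
}

#' Simulate a pooled expression table with a planted silent fraction
#'
#' A `silent_fraction` share of genes (rounded) receives pooled counts drawn
#' uniformly from `[0, 5)` — below the default expression filter — while the
#' rest draw from a log-normal with mean `active_mean` (sdlog 0.7, a typical
#' pooled-count dispersion that keeps the active mass clear of the filter).
#'
#' @param genes Character vector of gene ids.
#' @param silent_fraction Fraction of genes planted silent, in `[0, 1]`.
#' @param active_mean Mean pooled count of active genes.
#' @param seed Integer seed.
#' @return List: `table` (tibble `gene_id`, `pooled_count`) and `truth`
#'   (character vector of silent genes).
#' @export
simulate_expression <- function(genes, silent_fraction = 0.2,
                                active_mean = 100, seed = 1) {
  if (!(silent_fraction >= 0 && silent_fraction <= 1)) {
    stop("silent_fraction must be in [0, 1]", call. = FALSE)
  }
  stopifnot(active_mean > 0)
  genes <- as.character(genes)
  with_seed(fanout_seed(seed, "expression"), {
    n <- length(genes)
    silent <- sort(sample(genes, round(silent_fraction * n)))
    counts <- stats::rlnorm(n, meanlog = log(active_mean) - 0.7^2 / 2,
                            sdlog = 0.7)
    counts[match(silent, genes)] <- stats::runif(length(silent), 0, 5)
    list(table = tibble::tibble(gene_id = genes, pooled_count = counts),
         truth = silent)
  })
}

#' Simulate per-element repeat divergence records with planted fractions
#'
#' Utility for landscape tests and demos: element lengths per class are
#' chosen so each class occupies exactly its planted genome fraction, and
#' divergences are drawn uniformly from the class's age window.
#'
#' @param class_fractions Named numeric vector: class/family -> fraction of
#'   the genome covered.
#' @param genome_size Genome size in bp.
#' @param n_elements_per_class Elements per class (lengths equal within a
#'   class, up to rounding that conserves total bp).
#' @param divergence_range Length-2 range of Kimura % divergence, or a list
#'   of per-class ranges named by class.
#' @param seed Integer seed.
#' @return List: `records` (tibble) and `truth` (`class_fractions`).
#' @export
simulate_repeats <- function(class_fractions, genome_size,
                             n_elements_per_class = 50,
                             divergence_range = c(0, 50), seed = 1) {
  stopifnot(!is.null(names(class_fractions)), all(class_fractions > 0),
            genome_size > 0)
  with_seed(fanout_seed(seed, "repeats"), {
    rows <- lapply(names(class_fractions), function(cl) {
      total <- round(class_fractions[[cl]] * genome_size)
      n <- n_elements_per_class
      lens <- rep(total %/% n, n)
      lens[seq_len(total %% n)] <- lens[seq_len(total %% n)] + 1L
      rng <- if (is.list(divergence_range)) divergence_range[[cl]] else
        divergence_range
      tibble::tibble(class_family = cl, length_bp = as.integer(lens),
                     kimura_pct = stats::runif(n, rng[1], rng[2]))
    })
    list(records = dplyr::bind_rows(rows), truth = class_fractions)
  })
}
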