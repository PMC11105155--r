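# Rule-based classification of proteins by their domain-content multiset.
# Rules express the expected Pfam architecture of curated candidates, e.g.
# a white-collar 1 candidate carries exactly one each of GATA, PAS_3 and
# PAS_9, while white-collar 2 carries GATA and PAS_3 but no PAS_9.

#' Construct a domain-architecture rule
#'
#' A rule is satisfied by a protein's domain-count multiset when every
#' required entry holds (`exact` means equality, `min` means at least),
#' no forbidden domain is present, and each alternatives set contributes at
#' least one member.
#'
#' @param name Rule name.
#' @param required Named list: domain id -> either a bare number (treated as
#'   a minimum) or a list/vector with elements `count` and `mode`
#'   (`"exact"` or `"min"`). Counts must be >= 1.
#' @param forbidden Character vector of domain ids that must be absent.
#' @param alternatives List of character vectors; at least one member of each
#'   vector must be present (count >= 1).
#' @return An object of class `architecture_rule`.
#' @export
architecture_rule <- function(name, required = list(), forbidden = character(),
                              alternatives = list()) {
  stopifnot(is.character(name), length(name) == 1)
  req <- lapply(required, function(spec) {
    if (is.numeric(spec) && length(spec) == 1) {
      list(count = as.integer(spec), mode = "min")
    } else {
      spec <- as.list(spec)
      list(count = as.integer(spec$count),
           mode = match.arg(spec$mode %||% "min", c("exact", "min")))
    }
  })
  if (any(vapply(req, function(r) r$count < 1, logical(1)))) {
    stop("required counts must be >= 1", call. = FALSE)
  }
  forbidden <- as.character(forbidden)
  if (length(intersect(names(req), forbidden))) {
    stop("required and forbidden domains must be disjoint", call. = FALSE)
  }
  alternatives <- lapply(alternatives, as.character)
  structure(list(name = name, required = req, forbidden = forbidden,
                 alternatives = alternatives),
            class = "architecture_rule")
}

#' Evaluate a rule against one protein's domain profile
#'
#' @param profile Named integer vector: domain id -> occurrences within the
#'   protein (absent domains may simply be missing).
#' @param rule An [architecture_rule].
#' @return `TRUE` iff the profile satisfies the rule.
#' @export
evaluate_rule <- function(profile, rule) {
  stopifnot(inherits(rule, "architecture_rule"))
  cnt <- function(d) if (d %in% names(profile)) as.integer(profile[[d]]) else 0L
  for (d in names(rule$required)) {
    r <- rule$required[[d]]
    ok <- if (r$mode == "exact") cnt(d) == r$count else cnt(d) >= r$count
    if (!ok) return(FALSE)
  }
  for (d in rule$forbidden) {
    if (cnt(d) > 0) return(FALSE)
  }
  for (alt in rule$alternatives) {
    if (!any(vapply(alt, function(d) cnt(d) > 0, logical(1)))) return(FALSE)
  }
  TRUE
}

#' Built-in curated rule sets
#'
#' Loads the curated rule sets shipped with the package (a versioned YAML
#' config, so rule sets can be extended without code changes):
#' \describe{
#'   \item{circadian}{FRQ (>= 1 FRQ), WC1 (exactly one each of GATA, PAS_3,
#'     PAS_9), WC2 (exactly one GATA and one PAS_3, no PAS_9), Rhodopsin
#'     (exactly one 7tm_1).}
#'   \item{rnai}{RDRP (RdRP), Dicer (Dicer_dimer), Ago (PAZ and Piwi),
#'     Dicer_Alt (Ribonuclease_3 plus either DEAD or PAZ).}
#'   \item{rid}{RID_candidate: at least two DNA_methylase domains. Counts
#'     stand in for tandem adjacency, which needs domain coordinates the
#'     input table does not carry.}
#'   \item{light}{Single-domain surveys (>= 1) for Bac_rhodopsin,
#'     DNA_photolyase, FAD_binding_7, PHY, GpcrRhopsn4 and GAF.}
#' }
#'
#' @param path Path to a rules YAML; defaults to the shipped config.
#' @param min_counts If `TRUE`, relax every `exact` requirement to a minimum
#'   (for sensitivity analyses).
#' @return Named list of rule sets, each a named list of [architecture_rule]s.
#' @export
builtin_rulesets <- function(path = system.file("extdata", "rulesets.yaml",
                                                package = "entomocomp"),
                             min_counts = FALSE) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(ruleset) {
    rules <- lapply(names(ruleset), function(rn) {
      spec <- ruleset[[rn]]
      req <- spec$required %||% list()
      if (min_counts) {
        req <- lapply(req, function(r) {
          if (is.list(r)) r$mode <- "min"
          r
        })
      }
      architecture_rule(rn, required = req,
                        forbidden = unlist(spec$forbidden) %||% character(),
                        alternatives = spec$alternatives %||% list())
    })
    stats::setNames(rules, names(ruleset))
  })
}

#' Per-protein domain profiles from an annotation table
#'
#' Occurrences are row counts, so a protein annotated with three copies of a
#' domain has profile count 3 for it.
#'
#' @param x A [domain_annotation] object or a data frame with `species`,
#'   `gene_id`, `domain_id`.
#' @return Tibble `species`, `gene_id`, `domain_id`, `n` (occurrences).
#' @export
protein_profiles <- function(x) {
  ann <- if (inherits(x, "domain_annotation")) x$annotations else tibble::as_tibble(x)
  dplyr::count(ann, .data$species, .data$gene_id, .data$domain_id, name = "n")
}

#' Classify a proteome against a rule set
#'
#' Every protein is evaluated against every rule; a protein may satisfy
#' several rules and is counted once for each. The result is deterministic.
#'
#' @param x A [domain_annotation] object (or profile data frame accepted by
#'   [protein_profiles()]).
#' @param rules A named list of [architecture_rule]s (one rule set as
#'   returned by [builtin_rulesets()]), or a single rule.
#' @return Tibble `species`, `rule`, `n` (matching proteins; zero rows are
#'   kept so every species x rule combination appears).
#' @export
classify_proteome <- function(x, rules) {
  if (inherits(rules, "architecture_rule")) {
    rules <- stats::setNames(list(rules), rules$name)
  }
  stopifnot(all(vapply(rules, inherits, logical(1), "architecture_rule")))
  prof <- protein_profiles(x)
  species <- if (inherits(x, "domain_annotation")) names(x$totals) else unique(prof$species)
  by_gene <- split(prof, paste(prof$species, prof$gene_id, sep = "\r"))
  hits <- lapply(by_gene, function(g) {
    counts <- stats::setNames(g$n, g$domain_id)
    ok <- vapply(rules, evaluate_rule, logical(1), profile = counts)
    if (!any(ok)) return(NULL)
    tibble::tibble(species = g$species[1], rule = names(rules)[ok])
  })
  tallied <- dplyr::count(dplyr::bind_rows(hits), .data$species, .data$rule,
                          name = "n")
  grid <- tidyr::expand_grid(species = species, rule = names(rules))
  out <- dplyr::left_join(grid, tallied, by = c("species", "rule"))
  out$n <- as.integer(tidyr::replace_na(out$n, 0L))
  out
}
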