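# Repeat composition and divergence landscapes from per-element records
# (class/family label, aligned bp, Kimura % divergence from family consensus).

#' Kimura two-parameter distance
#'
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` for transition proportion `P`
#' and transversion proportion `Q`. Outside the model's domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance is undefined
#' (saturation) and an error is raised. Plain K2P only; the CpG-adjusted
#' variant RepeatMasker also offers is not implemented.
#'
#' @param P Transition proportion(s), `>= 0`.
#' @param Q Transversion proportion(s), `>= 0`.
#' @return Numeric vector of distances (substitutions per site).
#' @export
kimura2p <- function(P, Q) {
  if (any(P < 0) || any(Q < 0)) {
    stop("P and Q must be non-negative", call. = FALSE)
  }
  t1 <- 1 - 2 * P - Q
  t2 <- 1 - 2 * Q
  if (any(t1 <= 0) || any(t2 <= 0)) {
    stop("distance undefined (saturation)", call. = FALSE)
  }
  -0.5 * log(t1 * sqrt(t2))
}

#' Repeat composition table
#'
#' Genome fraction per repeat class/family: summed aligned bp over genome
#' size. In a multi-species call (records carry a `species` column and
#' `genome_size` is named by species) a class is flagged `hidden` only when
#' its fraction fails to exceed `show_threshold` in every species — the
#' display filter used for composition bar plots (default: 0.1% of the
#' genome).
#'
#' @param records Repeat record tibble (`class_family`, `length_bp`,
#'   `kimura_pct`, optional `species`).
#' @param genome_size Genome size in bp; a named vector per species for
#'   multi-species records.
#' @param show_threshold Fraction of the genome a class must exceed in at
#'   least one species to be shown (default 0.001).
#' @return Tibble `class_family` (+ `species` if present), `bp`,
#'   `pct_genome`, `hidden`.
#' @export
composition_table <- function(records, genome_size, show_threshold = 0.001) {
  records <- validate_repeat_records_any(records)
  if (any(genome_size <= 0)) stop("genome_size must be positive", call. = FALSE)
  if (!nrow(records)) {
    return(tibble::tibble(class_family = character(), species = character(),
                          bp = integer(), pct_genome = double(),
                          hidden = logical()))
  }
  multi <- "species" %in% names(records)
  if (!multi) records$species <- "genome"
  gs <- if (!is.null(names(genome_size))) genome_size else
    stats::setNames(rep(genome_size, length(unique(records$species))),
                    unique(records$species))
  agg <- dplyr::summarise(dplyr::group_by(records, .data$class_family,
                                          .data$species),
                          bp = sum(.data$length_bp), .groups = "drop")
  agg$pct_genome <- as.numeric(100 * agg$bp / gs[agg$species])
  shown <- dplyr::summarise(dplyr::group_by(agg, .data$class_family),
                            shown = any(.data$pct_genome > 100 * show_threshold),
                            .groups = "drop")
  agg$hidden <- !shown$shown[match(agg$class_family, shown$class_family)]
  if (!multi) agg$species <- NULL
  agg
}

#' @noRd
validate_repeat_records_any <- function(records) {
  rec <- tibble::as_tibble(records)
  sp <- if ("species" %in% names(rec)) rec["species"] else NULL
  out <- validate_repeat_records(rec[c("class_family", "length_bp", "kimura_pct")])
  if (!is.null(sp)) out$species <- sp$species
  out
}

#' Repeat divergence landscape matrix
#'
#' Each element's aligned bp is added to the Kimura-divergence bin
#' `floor(kimura_pct / bin_width)` for its class (left-closed, right-open
#' width-`bin_width` bins indexed from 0, the convention of RepeatMasker's
#' landscape script); cell values are percent of the genome. Classes whose
#' total bp is below `other_threshold` of all repeat bp are merged into the
#' class `"Other"`, exactly conserving total repeat bp.
#'
#' @param records Repeat record tibble (`class_family`, `length_bp`,
#'   `kimura_pct`).
#' @param genome_size Genome size in bp.
#' @param bin_width Divergence bin width in percent (default 1).
#' @param other_threshold Fraction of total repeat bp below which a class is
#'   merged into `"Other"` (default 0.01).
#' @return Long-format tibble `class_family`, `bin` (integer index), `bp`,
#'   `pct_genome`.
#' @export
landscape_bins <- function(records, genome_size, bin_width = 1,
                           other_threshold = 0.01) {
  records <- validate_repeat_records_any(records)
  stopifnot(genome_size > 0, bin_width > 0)
  if (!nrow(records)) {
    return(tibble::tibble(class_family = character(), bin = integer(),
                          bp = integer(), pct_genome = double()))
  }
  total_bp <- sum(records$length_bp)
  class_bp <- tapply(records$length_bp, records$class_family, sum)
  minor <- names(class_bp)[class_bp < other_threshold * total_bp]
  records$class_family[records$class_family %in% minor] <- "Other"
  records$bin <- as.integer(floor(records$kimura_pct / bin_width))
  out <- dplyr::summarise(dplyr::group_by(records, .data$class_family, .data$bin),
                          bp = sum(.data$length_bp), .groups = "drop")
  out$pct_genome <- 100 * out$bp / genome_size
  dplyr::arrange(out, .data$class_family, .data$bin)
}
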