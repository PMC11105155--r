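# Sliding-window detection of repeat-induced point mutation (RIP).
#
# RIP converts C to T at (mostly) CpA dinucleotides within duplicated
# sequence, leaving an excess of TpA and a deficit of CpA/TpG. The composite
# RIP index combines the product index TpA/ApT with the substrate index
# (CpA + TpG)/(ApC + GpT): composite = product - substrate. Windows with a
# composite index strictly greater than zero are scored as RIPped.

DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          function(a, b) paste0(a, b)))

#' Count overlapping dinucleotides in a window
#'
#' All 16 dinucleotides over `{A,C,G,T}` are counted at overlapping positions;
#' any pair containing `N` is skipped, so the counts sum to the number of
#' N-free overlapping positions.
#'
#' @param seq A single sequence: character scalar or [Biostrings::DNAString]
#'   over `{A,C,G,T,N}`.
#' @return Named integer vector of the 16 dinucleotide counts.
#' @export
count_dinucleotides <- function(seq) {
  if (is.character(seq)) {
    stopifnot(length(seq) == 1)
    if (!nzchar(seq)) {
      return(stats::setNames(integer(16), sort(DINUCS)))
    }
    seq <- Biostrings::DNAString(toupper(seq))
  }
  Biostrings::oligonucleotideFrequency(seq, width = 2)
}

#' @noRd
safe_ratio <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' RIP indices from dinucleotide counts
#'
#' Product index TpA/ApT, substrate index (CpA + TpG)/(ApC + GpT), and their
#' difference, the composite index. An index with a zero denominator is
#' undefined (`NA`); the composite is undefined when either term is.
#'
#' @param counts Named numeric vector of dinucleotide counts (as from
#'   [count_dinucleotides()]); only `TA, AT, CA, TG, AC, GT` are used.
#' @return Named numeric vector `product_index`, `substrate_index`,
#'   `composite_index` (with `NA` for undefined).
#' @export
rip_indices <- function(counts) {
  need <- c("TA", "AT", "CA", "TG", "AC", "GT")
  if (!all(need %in% names(counts))) {
    stop("counts must include ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(counts[need] < 0)) stop("counts must be non-negative", call. = FALSE)
  product <- safe_ratio(counts[["TA"]], counts[["AT"]])
  substrate <- safe_ratio(counts[["CA"]] + counts[["TG"]],
                          counts[["AC"]] + counts[["GT"]])
  c(product_index = product, substrate_index = substrate,
    composite_index = product - substrate)
}

#' Scan a genome in sliding windows and compute RIP indices
#'
#' Windows of `window_bp` are placed at offsets `0, step_bp, 2*step_bp, ...`
#' on each contig (0-based, half-open); a window is kept only if it fits
#' entirely on the contig, so trailing partials are skipped and contigs
#' shorter than `window_bp` contribute no windows. Scanning is single strand:
#' all three indices are invariant under reverse complement (TpA and ApT are
#' self-complementary classes; CpA/TpG and ApC/GpT are complementary pairs).
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param window_bp Window length in bp (default 1000).
#' @param step_bp Offset between window starts in bp (default 500).
#' @return A tibble with one row per window: `contig`, `start`, `end`,
#'   `product_index`, `substrate_index`, `composite_index`, `ripped`
#'   (composite defined and > 0), ordered by (contig, start).
#' @export
scan_windows <- function(genome, window_bp = 1000, step_bp = 500) {
  if (!is_count(window_bp) || window_bp < 2) {
    stop("window_bp must be an integer >= 2", call. = FALSE)
  }
  if (!is_count(step_bp) || step_bp < 1 || step_bp > window_bp) {
    stop("step_bp must satisfy 1 <= step_bp <= window_bp", call. = FALSE)
  }
  genome <- if (methods::is(genome, "DNAStringSet")) genome else as_genome(genome)
  per_contig <- lapply(seq_along(genome), function(i) {
    len <- Biostrings::width(genome)[i]
    if (len < window_bp) return(NULL)
    starts <- seq.int(0L, len - window_bp, by = step_bp)
    views <- Biostrings::Views(genome[[i]], start = starts + 1L,
                               width = window_bp)
    d <- Biostrings::oligonucleotideFrequency(views, width = 2)
    product <- safe_ratio(d[, "TA"], d[, "AT"])
    substrate <- safe_ratio(d[, "CA"] + d[, "TG"], d[, "AC"] + d[, "GT"])
    composite <- product - substrate
    tibble::tibble(
      contig = names(genome)[i],
      start = as.integer(starts),
      end = as.integer(starts + window_bp),
      product_index = unname(product),
      substrate_index = unname(substrate),
      composite_index = unname(composite),
      ripped = !is.na(composite) & composite > 0
    )
  })
  out <- dplyr::bind_rows(per_contig)
  if (!nrow(out)) {
    out <- tibble::tibble(contig = character(), start = integer(),
                          end = integer(), product_index = double(),
                          substrate_index = double(), composite_index = double(),
                          ripped = logical())
  }
  out
}

#' Summarize the fraction of a genome showing RIP
#'
#' Counts windows whose composite index is strictly greater than zero. With
#' `denominator = "all"` (the default) windows with undefined indices (e.g.
#' N-rich gaps) stay in the denominator and never in the numerator, which is
#' conservative: it cannot inflate the RIP estimate. `"defined"` restricts
#' the denominator to windows whose composite index is defined.
#'
#' @param windows Window tibble from [scan_windows()].
#' @param denominator `"all"` or `"defined"`.
#' @return One-row tibble: `total_windows`, `defined_windows`,
#'   `ripped_windows`, `pct_ripped` (percent), `denominator`.
#' @export
genome_rip_summary <- function(windows, denominator = c("all", "defined")) {
  denominator <- match.arg(denominator)
  total <- nrow(windows)
  defined <- sum(!is.na(windows$composite_index))
  ripped <- sum(windows$ripped)
  denom <- if (denominator == "all") total else defined
  pct <- if (denom > 0) 100 * ripped / denom else NA_real_
  if (total == 0) {
    warning("no windows scanned; pct_ripped undefined", call. = FALSE)
  }
  tibble::tibble(total_windows = total, defined_windows = defined,
                 ripped_windows = ripped, pct_ripped = pct,
                 denominator = denominator)
}
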