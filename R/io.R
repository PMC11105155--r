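# Readers and writers for the external formats the pipeline consumes:
# FASTA assemblies, per-gene domain annotation tables, OrthoFinder-style
# orthogroup tables, repeat divergence tables, and pooled expression counts.
# Coordinates everywhere are 0-based, half-open (BED convention).

IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Coerce sequences to a validated genome
#'
#' Case-folds sequences to upper case, maps IUPAC ambiguity codes to `N`
#' (real assemblies contain them; the RIP scan must tolerate them), and
#' rejects anything outside `{A,C,G,T,N}` after that mapping. The number of
#' ambiguity codes replaced is recorded in `S4Vectors::metadata()` under
#' `n_ambiguous` and reported with a message.
#'
#' @param x A named character vector of contig sequences or a
#'   [Biostrings::DNAStringSet].
#' @return A [Biostrings::DNAStringSet] over the alphabet `{A,C,G,T,N}`.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x)) {
    seqs <- x
  } else {
    stop("`x` must be a named character vector or a DNAStringSet", call. = FALSE)
  }
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("every contig must have a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate contig id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("contig ", ids[!nzchar(seqs)][1], " has an empty sequence", call. = FALSE)
  }
  seqs <- toupper(seqs)
  amb_pattern <- paste0("[", paste(IUPAC_AMBIGUITY, collapse = ""), "]")
  n_amb <- sum(nchar(seqs) - nchar(gsub(amb_pattern, "", seqs)))
  if (n_amb > 0) {
    seqs <- gsub(amb_pattern, "N", seqs)
    message("mapped ", n_amb, " IUPAC ambiguity code(s) to N")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1], regexpr("[^ACGTN]", seqs[bad][1]))
    stop("illegal character '", ch, "' in contig ", ids[bad][1], call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$n_ambiguous <- n_amb
  out
}

# Locate the first sequence line of a FASTA file carrying a character that is
# not a base, an IUPAC code or whitespace, for error messages that name a line.
#' @noRd
find_bad_fasta_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seq_lines <- !startsWith(lines, ">")
  bad <- grepl("[^ACGTNRYSWKMBDHVacgtnryswkmbdhv[:space:]]", lines) & seq_lines
  if (any(bad)) which(bad)[1] else NA_integer_
}

#' Read a genome assembly from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] and then validates the result with
#' [as_genome()]: contig ids must be unique and non-empty, sequences are
#' case-folded, ambiguity codes become `N` (count logged), and any other
#' character is a hard error naming the offending line.
#'
#' @param path Path to a (optionally line-wrapped) multi-record FASTA file.
#' @return A validated [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  bad_letters <- function(cond) {
    # Biostrings drops invalid letters with a warning; treat that as fatal
    line <- find_bad_fasta_line(path)
    if (!is.na(line)) {
      stop("illegal character in FASTA file ", path, " at line ", line,
           call. = FALSE)
    }
    stop("failed to parse FASTA file ", path, ": ", conditionMessage(cond),
         call. = FALSE)
  }
  raw <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
             error = bad_letters),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        bad_letters(w)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(raw) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  # keep only the first whitespace-delimited token of each header
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw))) {
    stop("duplicate contig id: ", names(raw)[duplicated(names(raw))][1],
         call. = FALSE)
  }
  gap <- Biostrings::letterFrequency(raw, letters = "-+.", OR = 0)
  if (any(rowSums(gap) > 0)) {
    line <- find_bad_fasta_line(path)
    stop("illegal character in FASTA file ", path,
         if (!is.na(line)) paste0(" at line ", line), call. = FALSE)
  }
  as_genome(raw)
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  genome <- if (methods::is(genome, "DNAStringSet")) genome else as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

DOMAIN_TYPES <- c("PFAM", "MEROPS", "CAZY")

#' Construct a validated domain annotation table
#'
#' One row per (species, gene, domain) occurrence; rows may repeat for
#' multi-copy domains. Proteome totals are supplied explicitly rather than
#' inferred from distinct gene ids, because genes with zero annotated domains
#' still belong to enrichment-test denominators.
#'
#' @param annotations A data frame with columns `species`, `gene_id`,
#'   `domain_id`, `domain_type` (one of `PFAM`, `MEROPS`, `CAZY`) and
#'   `secreted` (logical, constant within a gene).
#' @param totals Named numeric vector: annotated proteome size per species.
#' @return An object of class `domain_annotation`: a list with elements
#'   `annotations` (tibble) and `totals` (named integer vector).
#' @export
domain_annotation <- function(annotations, totals) {
  annotations <- tibble::as_tibble(annotations)
  need <- c("species", "gene_id", "domain_id", "domain_type", "secreted")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  annotations <- annotations[need]
  if (is.character(annotations$secreted) || is.numeric(annotations$secreted)) {
    annotations$secreted <- as.logical(type.convert(as.character(annotations$secreted),
                                                    as.is = TRUE))
  }
  if (anyNA(annotations$secreted)) {
    stop("secreted flag must be TRUE/FALSE", call. = FALSE)
  }
  bad_type <- setdiff(unique(annotations$domain_type), DOMAIN_TYPES)
  if (length(bad_type)) {
    stop("unknown domain_type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  flags <- unique(annotations[c("species", "gene_id", "secreted")])
  dup <- duplicated(flags[c("species", "gene_id")])
  if (any(dup)) {
    stop("inconsistent secreted flag for gene ", flags$gene_id[dup][1],
         call. = FALSE)
  }
  if (is.null(names(totals)) || any(!nzchar(names(totals)))) {
    stop("`totals` must be a named vector of proteome sizes", call. = FALSE)
  }
  totals <- stats::setNames(as.integer(totals), names(totals))
  sp <- unique(annotations$species)
  miss_sp <- setdiff(sp, names(totals))
  if (length(miss_sp)) {
    stop("no proteome total for species: ", paste(miss_sp, collapse = ", "),
         call. = FALSE)
  }
  n_genes <- table(unique(annotations[c("species", "gene_id")])$species)
  too_small <- names(n_genes)[n_genes > totals[names(n_genes)]]
  if (length(too_small)) {
    stop("proteome total for ", too_small[1],
         " is smaller than its number of annotated genes", call. = FALSE)
  }
  structure(list(annotations = annotations, totals = totals),
            class = "domain_annotation")
}

#' Read a per-gene domain annotation table
#'
#' Expects a TSV with header columns `species`, `gene_id`, `domain_id`,
#' `domain_type` and `secreted`, as produced downstream of Pfam/MEROPS/CAZy
#' annotation. Proteome totals come from a companion two-column TSV
#' (`species`, `proteome_total`) or a named vector.
#'
#' @param path Path to the annotation TSV.
#' @param totals Path to a totals TSV, or a named numeric vector.
#' @return A [domain_annotation] object.
#' @export
read_domain_table <- function(path, totals) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (is.character(totals) && length(totals) == 1 && is.null(names(totals))) {
    tt <- readr::read_tsv(totals, show_col_types = FALSE,
                          col_types = readr::cols())
    if (!all(c("species", "proteome_total") %in% names(tt))) {
      stop("totals file needs columns species, proteome_total", call. = FALSE)
    }
    totals <- stats::setNames(tt$proteome_total, tt$species)
  }
  domain_annotation(tab, totals)
}

#' Write a domain annotation table (and its proteome totals)
#'
#' @param x A [domain_annotation] object.
#' @param path Output TSV path for the annotation rows.
#' @param totals_path Output TSV path for the proteome totals.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(x, path, totals_path) {
  stopifnot(inherits(x, "domain_annotation"))
  readr::write_tsv(x$annotations, path)
  readr::write_tsv(tibble::tibble(species = names(x$totals),
                                  proteome_total = unname(x$totals)),
                   totals_path)
  invisible(path)
}

#' Construct a validated orthogroup table
#'
#' @param genes Data frame with columns `og_id`, `species`, `gene_id`
#'   (one row per gene membership).
#' @param unassigned Data frame with columns `species`, `gene_id` for genes
#'   that clustered with no orthogroup. May be empty.
#' @param species Character vector of species covered (defaults to those seen).
#' @return An object of class `orthogroup_table`: list with tibbles `genes`
#'   and `unassigned` plus the `species` vector.
#' @export
orthogroup_table <- function(genes, unassigned = NULL, species = NULL) {
  genes <- tibble::as_tibble(genes)[c("og_id", "species", "gene_id")]
  if (is.null(unassigned)) {
    unassigned <- tibble::tibble(species = character(), gene_id = character())
  }
  unassigned <- tibble::as_tibble(unassigned)[c("species", "gene_id")]
  species <- species %||% sort(unique(c(genes$species, unassigned$species)))
  key <- paste(genes$species, genes$gene_id)
  dup <- duplicated(key) & !duplicated(paste(key, genes$og_id))
  if (any(dup)) {
    stop("gene ", genes$gene_id[dup][1], " appears in two orthogroups",
         call. = FALSE)
  }
  both <- intersect(paste(genes$species, genes$gene_id),
                    paste(unassigned$species, unassigned$gene_id))
  if (length(both)) {
    stop("gene listed both in an orthogroup and as unassigned: ",
         sub("^\\S+ ", "", both[1]), call. = FALSE)
  }
  iso <- grepl("-T\\d+$", c(genes$gene_id, unassigned$gene_id))
  if (any(iso)) {
    base <- sub("-T\\d+$", "", c(genes$gene_id, unassigned$gene_id)[iso])
    if (anyDuplicated(base)) {
      warning("gene ids look like transcript isoforms (suffix -T<n>) with ",
              "duplicated gene stems; collapse to one peptide per gene first",
              call. = FALSE)
    }
  }
  structure(list(genes = genes, unassigned = unassigned, species = species),
            class = "orthogroup_table")
}

#' @noRd
parse_orthogroup_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty orthogroup file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  species <- header[-1]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    cells <- rows[[i]]
    length(cells) <- length(header)
    og <- cells[1]
    parts <- lapply(cells[-1], function(cell) {
      if (is.na(cell) || !nzchar(trimws(cell))) return(character())
      trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    n <- lengths(parts)
    out[[i]] <- tibble::tibble(
      og_id = og,
      species = rep(species, n),
      gene_id = unlist(parts, use.names = FALSE) %||% character()
    )
  }
  list(species = species, genes = dplyr::bind_rows(out))
}

#' Read OrthoFinder-style orthogroup tables
#'
#' Parses the `Orthogroups.tsv` dialect (header row of species names, first
#' column the orthogroup id, cells comma-separated gene lists; empty cells
#' mean no genes) and optionally merges an `Orthogroups_UnassignedGenes.tsv`
#' companion into the per-species unassigned gene lists.
#'
#' @param path Path to the orthogroups TSV.
#' @param unassigned_path Optional path to the unassigned-genes TSV.
#' @return An [orthogroup_table] object.
#' @export
read_orthogroups <- function(path, unassigned_path = NULL) {
  parsed <- parse_orthogroup_tsv(path)
  una <- NULL
  if (!is.null(unassigned_path)) {
    pu <- parse_orthogroup_tsv(unassigned_path)
    una <- pu$genes[c("species", "gene_id")]
  }
  orthogroup_table(parsed$genes, una,
                   species = union(parsed$species,
                                   if (is.null(una)) character() else unique(una$species)))
}

#' Write an orthogroup table in the OrthoFinder dialect
#'
#' @param x An [orthogroup_table].
#' @param path Output path for the orthogroups TSV.
#' @param unassigned_path Optional output path for the unassigned-genes TSV.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(x, path, unassigned_path = NULL) {
  stopifnot(inherits(x, "orthogroup_table"))
  ogs <- unique(x$genes$og_id)
  header <- paste(c("Orthogroup", x$species), collapse = "\t")
  cells <- tapply(x$genes$gene_id,
                  list(factor(x$genes$og_id, levels = ogs),
                       factor(x$genes$species, levels = x$species)),
                  paste, collapse = ", ")
  cells[is.na(cells)] <- ""
  body <- vapply(seq_along(ogs), function(i) {
    paste(c(ogs[i], cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  if (!is.null(unassigned_path)) {
    un <- x$unassigned
    header2 <- paste(c("Orthogroup", x$species), collapse = "\t")
    rows <- vapply(seq_len(nrow(un)), function(i) {
      cells <- rep("", length(x$species))
      cells[match(un$species[i], x$species)] <- un$gene_id[i]
      paste(c(sprintf("UN%06d", i - 1), cells), collapse = "\t")
    }, character(1))
    writeLines(c(header2, rows), unassigned_path)
  }
  invisible(path)
}

#' Read a per-element repeat divergence table
#'
#' A simplified three-column TSV distilled from RepeatMasker divergence
#' output: `class_family`, `length_bp` (aligned bp, positive), `kimura_pct`
#' (percent divergence from family consensus, finite and non-negative).
#' A header row is detected automatically.
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per repeat element occurrence.
#' @export
read_repeat_divergence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty repeat divergence table: ", path, call. = FALSE)
    return(tibble::tibble(class_family = character(),
                          length_bp = integer(), kimura_pct = double()))
  }
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  if (has_header) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_shape <- which(lengths(parts) < 3)
  if (length(bad_shape)) {
    stop("malformed repeat record at data line ", bad_shape[1], call. = FALSE)
  }
  rec <- tibble::tibble(
    class_family = vapply(parts, `[[`, "", 1),
    length_bp = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2))),
    kimura_pct = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  )
  if (anyNA(rec$length_bp) || anyNA(rec$kimura_pct)) {
    stop("non-numeric length or divergence in ", path, call. = FALSE)
  }
  validate_repeat_records(rec)
}

#' @noRd
validate_repeat_records <- function(rec) {
  rec <- tibble::as_tibble(rec)
  stopifnot(all(c("class_family", "length_bp", "kimura_pct") %in% names(rec)))
  if (any(rec$length_bp <= 0)) stop("length_bp must be positive", call. = FALSE)
  if (any(!is.finite(rec$kimura_pct)) || any(rec$kimura_pct < 0)) {
    stop("kimura_pct must be finite and non-negative", call. = FALSE)
  }
  rec$length_bp <- as.integer(round(rec$length_bp))
  rec
}

#' Write a repeat divergence table
#' @param records Tibble of repeat records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_repeat_divergence <- function(records, path) {
  readr::write_tsv(validate_repeat_records(records), path)
  invisible(path)
}

#' Read a pooled expression count table
#'
#' TSV with header columns `gene_id` and `pooled_count` (estimated counts
#' summed over the pooled sample set). Counts must be non-negative and gene
#' ids unique.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `pooled_count`.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols())
  if (!all(c("gene_id", "pooled_count") %in% names(tab))) {
    stop("expression table needs columns gene_id, pooled_count", call. = FALSE)
  }
  tab <- tibble::as_tibble(tab)[c("gene_id", "pooled_count")]
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id in expression table", call. = FALSE)
  }
  if (any(!is.finite(tab$pooled_count)) || any(tab$pooled_count < 0)) {
    stop("pooled_count must be non-negative and finite", call. = FALSE)
  }
  tab
}

#' Write a pooled expression count table
#' @param expr Tibble with columns `gene_id`, `pooled_count`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(all(c("gene_id", "pooled_count") %in% names(expr)))
  readr::write_tsv(tibble::as_tibble(expr)[c("gene_id", "pooled_count")], path)
  invisible(path)
}

#' Write RIP scan windows as BED5
#'
#' Columns: contig, start, end (0-based half-open), the literal name `win`,
#' and the composite RIP index (`NA` when undefined) as score.
#'
#' @param windows Window tibble from [scan_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(windows$contig, windows$start, windows$end, "win",
                    windows$composite_index)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
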