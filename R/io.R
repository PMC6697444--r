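#' Read selection reads from FASTA/FASTQ
#'
#' Loads reads, validates the alphabet (only A, C, G, T, U allowed;
#' ambiguity codes are rejected), and maps U to T. Plain or gzip files are
#' accepted; the format is taken from the extension unless given.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"auto"` (default, from extension), `"fasta"` or
#'   `"fastq"`.
#' @return Tibble with columns `read_id`, `seq`. An empty file yields an
#'   empty tibble with a warning.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  set <- Biostrings::readBStringSet(path, format = format)
  if (length(set) == 0L) {
    warning("no records in ", path, call. = FALSE)
    return(tibble::tibble(read_id = character(0), seq = character(0)))
  }
  seqs <- normalize_seq(as.character(set))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("record(s) with characters outside {A,C,G,T,U} in ", path, ": ",
         paste(utils::head(names(set)[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  ids <- names(set)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(seqs))
  tibble::tibble(read_id = sub("\\s.*$", "", ids), seq = unname(seqs))
}

#' Write reads to FASTA or FASTQ
#'
#' FASTQ output uses a constant quality string (`"I"` per base), as the
#' simulated reads carry no quality information.
#'
#' @param reads Tibble with columns `read_id`, `seq`.
#' @param path Output path.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$read_id
  if (format == "fastq") {
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  } else {
    Biostrings::writeXStringSet(set, path, format = "fasta")
  }
  invisible(path)
}

#' Read/write titration tables
#'
#' Long TSV with columns `replicate_id`, `concentration_nM`, `signal`
#' (additional label columns such as `rna_label`, `protein_label`,
#' `partner_present` pass through untouched).
#'
#' @param path TSV path.
#' @return For the reader, a tibble; the writer returns `path` invisibly.
#' @export
read_titrations <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("replicate_id", "concentration_nM", "signal")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0L) {
    stop("titration table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_titrations
#' @param titrations Titration tibble.
#' @export
write_titrations <- function(titrations, path) {
  readr::write_tsv(titrations, path)
  invisible(path)
}

#' Write a pattern-count table as TSV
#'
#' One row per (dataset, pattern) with the per-+4-base compact:extended
#' ratio attached to the compact row of each pair; undefined ratios
#' (extended count 0) are written as `"."`. Patterns are printed with the
#' dot notation (`N` shown as `.`).
#'
#' @param count_table Output of [count_patterns()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(count_table, path) {
  ratios <- ratio_table(count_table)
  out <- count_table |>
    dplyr::left_join(
      dplyr::select(ratios, dplyr::all_of(c("dataset", "base4", "ratio"))),
      by = c("dataset", "base4")
    ) |>
    dplyr::mutate(
      pattern = chartr("N", ".", .data$pattern),
      terminal_au = paste0("+", .data$terminal_au, "U"),
      ratio = dplyr::if_else(.data$element_class == "compact" &
                               !is.na(.data$ratio),
                             as.character(signif(.data$ratio, 2)), ".")
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read/write gene fixtures
#'
#' Genes as FASTA plus a two-column annotation TSV (`gene_id`, `term`).
#'
#' @param genes Tibble with `gene_id`, `seq`.
#' @param annotations Tibble with `gene_id`, `term`.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_gene_fixtures <- function(genes, annotations, fasta_path,
                                annotation_path) {
  write_reads(dplyr::rename(genes, read_id = "gene_id"), fasta_path)
  readr::write_tsv(annotations, annotation_path)
  invisible(c(fasta_path, annotation_path))
}

#' @rdname write_gene_fixtures
#' @return For the reader, a list with `genes` and `annotations` tibbles.
#' @export
read_gene_fixtures <- function(fasta_path, annotation_path) {
  genes <- dplyr::rename(read_sequences(fasta_path), gene_id = "read_id")
  annotations <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                                 col_types = readr::cols(.default = "c"))
  list(genes = genes, annotations = annotations)
}
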