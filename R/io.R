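#' Collapse exon intervals into gene models
#'
#' Merges (possibly overlapping) 0-based half-open exon intervals per gene
#' with [IRanges::reduce()] and totals the merged lengths into
#' `exon_length`. Input that is already a gene-model table (has an
#' `exon_length` column) is validated and passed through.
#'
#' @param exons Tibble with `gene_id`, `chromosome`, `start`, `end`
#'   (0-based half-open), one row per exon; or an existing gene-model
#'   table.
#' @return Tibble with `gene_id`, `chromosome`, `exon_length`,
#'   `is_sex_chromosome`, one row per gene.
#' @export
#' @examples
#' ex <- tibble::tibble(gene_id = "g", chromosome = "autosome",
#'                      start = c(0L, 50L), end = c(100L, 150L))
#' as_gene_models(ex)$exon_length # 150: the overlap is merged
as_gene_models <- function(exons) {
  if ("exon_length" %in% names(exons)) {
    stopifnot(all(exons$exon_length > 0))
    if (!"is_sex_chromosome" %in% names(exons)) {
      exons$is_sex_chromosome <- is_sex_chrom(exons$chromosome)
    }
    return(exons)
  }
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(exons)))
  if (any(exons$start >= exons$end)) {
    stop("exon with start >= end (coordinates are 0-based half-open)",
         call. = FALSE)
  }
  merged <- dplyr::summarise(
    dplyr::group_by(exons, gene_id, chromosome),
    exon_length = sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = start + 1L, end = end)
    ))),
    .groups = "drop"
  )
  merged$is_sex_chromosome <- is_sex_chrom(merged$chromosome)
  merged[order(merged$gene_id), ]
}

is_sex_chrom <- function(chromosome) {
  tolower(chromosome) %in% c("chrx", "chry", "x", "y")
}

#' Read gene models from a BED file
#'
#' Expects at least four tab-separated columns: chrom, start, end, gene id
#' (BED convention, 0-based half-open). Overlapping exons of a gene are
#' merged; malformed lines (non-numeric coordinates, start >= end) raise
#' an error naming the line.
#'
#' @param path Path to the BED file.
#' @return Gene-model tibble, see [as_gene_models()].
#' @export
read_gene_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chromosome", "start", "end", "gene_id"),
    col_types = readr::cols(
      chromosome = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), gene_id = readr::col_character()
    ),
    comment = "#", progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble::tibble(gene_id = character(0), chromosome = character(0),
                          exon_length = integer(0),
                          is_sex_chromosome = logical(0)))
  }
  bad <- which(is.na(raw$start) | is.na(raw$end) | raw$start >= raw$end)
  if (length(bad)) {
    stop("malformed BED line(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  as_gene_models(raw)
}

#' Write gene models as BED
#'
#' @param exons Exon tibble (`gene_id`, `chromosome`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(exons, path) {
  readr::write_tsv(exons[, c("chromosome", "start", "end", "gene_id")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read and write FASTA references
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param path File path.
#' @param sequences A [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @return `read_fasta`: a `DNAStringSet`; `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read and write FASTQ read sets
#'
#' Reads are carried as tibbles (`read_id`, `sequence`); on write every
#' base gets a constant Sanger Q30 quality ("?").
#'
#' @param path File path.
#' @param reads Read tibble with `read_id` and `sequence`.
#' @return `read_fastq`: a tibble; `write_fastq`: `path`, invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = names(x), sequence = unname(as.character(x)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  qual <- Biostrings::BStringSet(
    vapply(nchar(reads$sequence),
           function(n) strrep("?", n), "")
  )
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a variant table (TSV or VCF)
#'
#' For TSV input, `column_map` maps the required record fields
#' (`sample_id`, `chromosome`, `position`, `ref_base`, `alt_base`,
#' `coverage`, `vaf`, `population_maf`) to the file's column names; fields
#' absent from the map and the file are filled with `NA`. For VCF input
#' (detected by the `.vcf` extension or `##fileformat` header), CHROM,
#' POS, REF and ALT are taken from the fixed columns and coverage / allele
#' frequency from the INFO fields `DP` and `AF`. Indels (multi-base REF or
#' ALT) are skipped with a message; rows with out-of-range VAF are
#' rejected with their row numbers.
#'
#' @param path Input path.
#' @param column_map Named character vector, field -> column name (TSV
#'   only).
#' @param sample_id Sample id to assign when the file carries none.
#' @return Tibble of variant records.
#' @export
read_variant_table <- function(path, column_map = NULL, sample_id = NULL) {
  first <- readLines(path, n = 1)
  is_vcf <- grepl("\\.vcf$", path) || startsWith(first, "##fileformat=VCF")
  if (is_vcf) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    header <- sub("^#", "", body[1])
    df <- utils::read.table(
      text = paste(body[-1], collapse = "\n"), sep = "\t",
      col.names = strsplit(header, "\t")[[1]], stringsAsFactors = FALSE
    )
    info_field <- function(info, key) {
      m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
      as.numeric(m)
    }
    out <- tibble::tibble(
      sample_id = sample_id %||% "sample_1",
      chromosome = as.character(df$CHROM),
      position = as.integer(df$POS),
      ref_base = df$REF,
      alt_base = df$ALT,
      coverage = info_field(df$INFO, "DP"),
      vaf = info_field(df$INFO, "AF"),
      population_maf = info_field(df$INFO, "MAF")
    )
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    fields <- c("sample_id", "chromosome", "position", "ref_base",
                "alt_base", "coverage", "vaf", "population_maf")
    map <- stats::setNames(fields, fields)
    if (!is.null(column_map)) map[names(column_map)] <- column_map
    missing <- setdiff(
      map[c("ref_base", "alt_base", "coverage", "vaf")], names(raw)
    )
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    out <- tibble::tibble(.rows = nrow(raw))
    for (f in fields) {
      out[[f]] <- if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else NA
    }
    # a column holding only "T"/"F" bases is type-guessed as logical
    for (f in c("ref_base", "alt_base")) {
      if (is.logical(out[[f]])) out[[f]] <- ifelse(out[[f]], "T", "F")
    }
    if (!is.null(sample_id)) out$sample_id <- sample_id
  }
  indel <- nchar(out$ref_base) != 1 | nchar(out$alt_base) != 1
  if (any(indel)) {
    message(sum(indel), " non-SNV record(s) skipped")
    out <- out[!indel, , drop = FALSE]
  }
  bad <- which(!is.na(out$vaf) & (out$vaf < 0 | out$vaf > 1))
  if (length(bad)) {
    stop("vaf outside [0, 1] in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  same <- which(out$ref_base == out$alt_base)
  if (length(same)) {
    stop("ref equals alt in row(s): ", paste(same, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read and write count tables
#'
#' Tab-separated gene-by-sample count matrices with a `gene_id` first
#' column.
#'
#' @param path File path.
#' @param counts Count tibble.
#' @return `read_counts_tsv`: a tibble; `write_counts_tsv`: `path`,
#'   invisibly.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
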