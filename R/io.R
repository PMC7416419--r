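#' Read a gene-taxonomy ("phylodist"-style) table
#'
#' Tab-separated, no header, four columns: gene id, contig id, percent
#' identity of the best taxonomic hit, and a semicolon-delimited lineage
#' string (possibly empty, meaning no taxonomic assignment). Lineages are
#' validated: a rank gap (empty internal field) is a parse error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `contig_id`, `percent_identity`,
#'   `lineage` (normalized string, `NA` if absent).
#' @export
read_gene_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(gene_id = character(), contig_id = character(),
                          percent_identity = numeric(), lineage = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # a trailing empty lineage field is dropped by strsplit; pad it back
  parts <- lapply(parts, function(p) if (length(p) == 3) c(p, "") else p)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0) {
    abort(sprintf("malformed gene-taxonomy row at line %d: expected 4 tab-separated fields",
                  bad[1]))
  }
  m <- do.call(rbind, parts)
  lin <- tryCatch(parse_lineage(m[, 4]), error = function(e) {
    abort(sprintf("gene-taxonomy lineage parse failure: %s", conditionMessage(e)))
  })
  tibble::tibble(
    gene_id = m[, 1],
    contig_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    lineage = lin
  )
}

#' Read a gene-to-KO annotation table
#'
#' Tab-separated with columns gene id, contig id, KO term(s). Both one row
#' per KO and a comma- or semicolon-delimited KO list in the third column are
#' accepted; the result is always one row per (gene, KO).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `contig_id`, `ko`.
#' @export
read_gene_ko <- function(path) {
  df <- readr::read_tsv(path, col_names = c("gene_id", "contig_id", "ko"),
                        col_types = "ccc", progress = FALSE)
  df |>
    dplyr::mutate(ko = strsplit(.data$ko, "[,;]\\s*")) |>
    tidyr::unnest("ko") |>
    dplyr::filter(nzchar(.data$ko)) |>
    dplyr::distinct()
}

#' Read a contig depth summary
#'
#' Tab-separated with a single header line and columns `contig_id`,
#' `length_bp`, `read_depth`. Contigs shorter than 200 bp or with negative
#' depth are rejected (only contigs above 200 bp enter the assembly), as are
#' duplicated contig ids.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `contig_id`, `length_bp` (integer),
#'   `read_depth` (double).
#' @export
read_contig_depths <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    contig_id = readr::col_character(),
    length_bp = readr::col_integer(),
    read_depth = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(df$contig_id)) {
    abort(sprintf("duplicated contig_id in %s: %s", path,
                  df$contig_id[duplicated(df$contig_id)][1]))
  }
  if (any(df$length_bp < 200L)) {
    abort("contig length below the 200 bp assembly floor")
  }
  if (any(df$read_depth < 0)) {
    abort("negative read depth")
  }
  df
}

#' Read sample metadata
#'
#' CSV with columns `sample_id`, `date`, `depth_code`, `filter_fraction_um`
#' and optional environmental columns (`depth_m`, `salinity_pct`,
#' `daylength_h`, `sunlight_h`, `air_temp_C`). The (date, depth, fraction)
#' triple must be unique and every depth code must be one of U1--U3, I,
#' L1--L3.
#'
#' @param path Path to the CSV file.
#' @return A tibble of sample metadata with a `season` column added.
#' @export
read_sample_meta <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    date = readr::col_date(),
    depth_code = readr::col_character(),
    filter_fraction_um = readr::col_double(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(df$depth_code %in% depth_codes())) {
    abort("unknown depth_code in sample metadata")
  }
  key <- paste(df$date, df$depth_code, df$filter_fraction_um)
  if (anyDuplicated(key)) {
    abort("duplicate (date, depth_code, filter_fraction) in sample metadata")
  }
  df$season <- lake_season(df$date)
  df
}

#' Read a nucleotide FASTA file
#'
#' @param path Path to a FASTA file of sequences over {A, C, G, T, N}.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- as.character(ss)
  if (any(grepl("[^ACGTN]", seqs))) {
    abort("non-nucleotide characters in FASTA (alphabet is A/C/G/T/N)")
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Write / read tabular results as TSV
#'
#' All tabular pipeline outputs are TSV with a single header line; missing
#' values serialize as empty strings. `read_result_table()` round-trips
#' `write_result_table()` output.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `write_result_table()` returns `path` invisibly;
#'   `read_result_table()` returns a tibble.
#' @export
write_result_table <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), na = c(""),
                  progress = FALSE)
}
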