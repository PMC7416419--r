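#' Coverage-weighted relative abundance per OTU per metagenome
#'
#' The relative abundance of an OTU in a metagenome is the summed coverage
#' (contig length x contig read depth) of the OTU's contigs divided by the
#' summed coverage of all contigs in that metagenome, times 100. The
#' denominator spans every contig — abundant OTUs, everything later grouped
#' as "Other", and the unassigned pool — so values are comparable across
#' metagenomes. Contigs not present in `bins` contribute to the reserved
#' `"unassigned"` column.
#'
#' @param contigs Tibble with `contig_id`, `sample_id`, `length_bp`,
#'   `read_depth`.
#' @param bins Tibble with `contig_id`, `otu_name` (from [bin_otus()]).
#' @return A wide tibble: one row per `sample_id`, one column per OTU plus
#'   `"unassigned"`; cells are relative abundance in percent and each row
#'   sums to 100.
#' @export
relative_abundance <- function(contigs, bins) {
  stopifnot(all(c("contig_id", "sample_id", "length_bp", "read_depth")
                %in% names(contigs)))
  cov <- contigs |>
    dplyr::mutate(coverage = as.numeric(.data$length_bp) * .data$read_depth) |>
    dplyr::left_join(dplyr::select(bins, "contig_id", "otu_name"),
                     by = "contig_id") |>
    dplyr::mutate(otu_name = dplyr::coalesce(.data$otu_name, "unassigned"))

  totals <- cov |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$coverage), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(sprintf("sample with zero total coverage: %s",
                  totals$sample_id[totals$total <= 0][1]))
  }

  long <- cov |>
    dplyr::group_by(.data$sample_id, .data$otu_name) |>
    dplyr::summarise(coverage = sum(.data$coverage), .groups = "drop") |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(ra = .data$coverage / .data$total * 100)

  long |>
    dplyr::select("sample_id", "otu_name", "ra") |>
    tidyr::pivot_wider(names_from = "otu_name", values_from = "ra",
                       values_fill = 0)
}

#' Peak relative abundance over a set of metagenomes
#'
#' The highest relative abundance each OTU attains over the scoped samples
#' (all samples, a season, a depth, a filter fraction, ...).
#'
#' @param table Abundance table from [relative_abundance()].
#' @param samples Optional character vector of sample ids delimiting the
#'   scope; default all rows. An empty scope is an error.
#' @return A tibble with columns `otu_name`, `peak_ra`.
#' @export
peak_relative_abundance <- function(table, samples = NULL) {
  if (!is.null(samples)) {
    table <- dplyr::filter(table, .data$sample_id %in% samples)
  }
  if (nrow(table) == 0) abort("peak relative abundance over an empty sample scope")
  table |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_name",
                        values_to = "ra") |>
    dplyr::group_by(.data$otu_name) |>
    dplyr::summarise(peak_ra = max(.data$ra), .groups = "drop")
}

#' Total abundance (summed coverage) per OTU
#'
#' @param contigs Tibble with `contig_id`, `sample_id`, `length_bp`,
#'   `read_depth`.
#' @param bins Tibble with `contig_id`, `otu_name`.
#' @param samples Optional sample-id scope; default all.
#' @return Tibble `otu_name`, `total_abundance`, descending.
#' @export
total_abundance <- function(contigs, bins, samples = NULL) {
  if (!is.null(samples)) {
    contigs <- dplyr::filter(contigs, .data$sample_id %in% samples)
  }
  contigs |>
    dplyr::inner_join(dplyr::select(bins, "contig_id", "otu_name"),
                      by = "contig_id") |>
    dplyr::group_by(.data$otu_name) |>
    dplyr::summarise(
      total_abundance = sum(as.numeric(.data$length_bp) * .data$read_depth),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_abundance))
}

#' Select abundant OTUs
#'
#' OTUs reaching a relative abundance of at least `threshold` percent
#' (inclusive) in one or more metagenomes are "abundant"; they are returned
#' in descending order of total abundance, the ordering used for community
#' overview figures.
#'
#' @inheritParams total_abundance
#' @param table Abundance table from [relative_abundance()].
#' @param threshold Percent relative abundance cut-off, default 1.
#' @return Character vector of abundant OTU names, by descending total
#'   abundance.
#' @export
select_abundant <- function(table, contigs, bins, threshold = 1.0) {
  peaks <- peak_relative_abundance(table)
  peaks <- dplyr::filter(peaks, .data$otu_name != "unassigned",
                         .data$peak_ra >= threshold)
  ord <- total_abundance(contigs, bins)
  ord$otu_name[ord$otu_name %in% peaks$otu_name]
}

#' Group non-abundant OTUs into domain-level "Other" columns
#'
#' Columns not in `abundant` (and not `"unassigned"`) are summed into
#' `"Other Bacteria"`, `"Other Archaea"`, `"Other Eukarya"` or
#' `"Other Viruses"` according to each OTU's domain. Row sums are preserved.
#'
#' @param table Abundance table from [relative_abundance()].
#' @param abundant Character vector of abundant OTU names to keep.
#' @param domains Tibble with `otu_name`, `domain` (one row per OTU; domains
#'   `Bacteria`, `Archaea`, `Eukaryota`/`Eukarya`, `Viruses`).
#' @return A wide tibble with the abundant OTUs, the four Other columns and
#'   `"unassigned"`.
#' @export
group_other <- function(table, abundant, domains) {
  other_label <- function(domain) {
    dplyr::case_match(domain,
      "Bacteria" ~ "Other Bacteria",
      "Archaea" ~ "Other Archaea",
      c("Eukaryota", "Eukarya") ~ "Other Eukarya",
      "Viruses" ~ "Other Viruses",
      .default = "Other Bacteria")
  }
  long <- table |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_name", values_to = "ra")
  dom <- dplyr::distinct(domains, .data$otu_name, .data$domain)
  long <- long |>
    dplyr::left_join(dom, by = "otu_name") |>
    dplyr::mutate(column = dplyr::case_when(
      .data$otu_name == "unassigned" ~ "unassigned",
      .data$otu_name %in% abundant ~ .data$otu_name,
      TRUE ~ other_label(.data$domain)
    ))
  wide <- long |>
    dplyr::group_by(.data$sample_id, .data$column) |>
    dplyr::summarise(ra = sum(.data$ra), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "column", values_from = "ra",
                       values_fill = 0)
  for (col in c("Other Bacteria", "Other Archaea", "Other Eukarya",
                "Other Viruses")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  ord <- c("sample_id", intersect(abundant, names(wide)),
           "Other Bacteria", "Other Archaea", "Other Eukarya",
           "Other Viruses", intersect("unassigned", names(wide)))
  wide[, ord]
}
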