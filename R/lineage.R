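#' Taxonomic ranks used throughout the package
#'
#' Lineages are semicolon-delimited strings over the seven canonical ranks,
#' domain first. A lineage may stop early (e.g. assigned only to family) but
#' may not skip a rank: a genus label implies family, order, and so on are
#' present. An absent lineage is represented by `NA`.
#'
#' @return Character vector of the seven rank names, domain to species.
#' @export
#' @examples
#' tax_ranks()
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Parse and validate lineage strings
#'
#' Splits semicolon-delimited lineage strings, trims trailing empty fields,
#' and enforces the contiguous-prefix rule (no internal rank gaps, at most
#' seven fields). Empty strings and `NA` become `NA` (absent lineage).
#'
#' @param x Character vector of lineage strings.
#' @return Character vector of normalized lineage strings (`NA` for absent).
#' @export
#' @examples
#' parse_lineage("Bacteria;Chlorobi;Chlorobia;Chlorobiales;Chlorobiaceae;Chlorobium")
parse_lineage <- function(x) {
  out <- vapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    # strsplit drops trailing empties already; also trim explicit ones
    while (length(parts) > 0 && !nzchar(parts[length(parts)])) {
      parts <- parts[-length(parts)]
    }
    if (length(parts) == 0) return(NA_character_)
    if (length(parts) > 7) {
      abort(sprintf("lineage '%s' has more than 7 ranks", s))
    }
    if (any(!nzchar(parts))) {
      abort(sprintf("lineage '%s' has a rank gap (empty internal field)", s))
    }
    paste(parts, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  out
}

lineage_fields <- function(x) {
  if (is.na(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Number of assigned ranks in a lineage
#' @param x Character vector of normalized lineage strings.
#' @return Integer vector, 0 for absent lineages.
#' @export
lineage_depth <- function(x) {
  ifelse(is.na(x), 0L, lengths(strsplit(x, ";", fixed = TRUE)))
}

#' Deepest assigned rank of a lineage
#'
#' @param x Character vector of normalized lineage strings.
#' @return Character vector of rank names; `"unassigned"` for absent lineages.
#' @export
#' @examples
#' lowest_rank("Bacteria;Cyanobacteria")  # "phylum"
#' lowest_rank(NA)                        # "unassigned"
lowest_rank <- function(x) {
  d <- lineage_depth(x)
  ifelse(d == 0L, "unassigned", tax_ranks()[pmax(d, 1L)])
}

#' Truncate a lineage to its first `depth` ranks
#' @param x Character vector of normalized lineage strings.
#' @param depth Integer, number of ranks to keep (1--7).
#' @return Character vector; `NA` where the lineage does not reach `depth`.
#' @export
lineage_prefix <- function(x, depth) {
  vapply(x, function(s) {
    f <- lineage_fields(s)
    if (length(f) < depth) return(NA_character_)
    paste(f[seq_len(depth)], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Label at the deepest assigned rank
#' @param x Character vector of normalized lineage strings.
#' @return Character vector of taxon labels; `NA` for absent lineages.
#' @export
lineage_label <- function(x) {
  vapply(x, function(s) {
    f <- lineage_fields(s)
    if (length(f) == 0) return(NA_character_)
    f[length(f)]
  }, character(1), USE.NAMES = FALSE)
}

#' Domain of a lineage
#' @param x Character vector of normalized lineage strings.
#' @return Character vector of domain labels; `NA` for absent lineages.
#' @export
lineage_domain <- function(x) lineage_prefix(x, 1L)
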