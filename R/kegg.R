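#' Per-sample KO abundance from contig read depths
#'
#' The abundance of a KO term in a metagenome is the sum of the read depths
#' of the distinct contigs carrying at least one gene annotated with that
#' KO. A contig counts once per KO regardless of how many of its genes carry
#' the term: the accounting is contig-based, not gene-based.
#'
#' @param contigs Tibble with `contig_id`, `sample_id`, `read_depth`.
#' @param gene_ko Tibble with `contig_id`, `ko` (one row per gene-KO pair;
#'   `gene_id` may be present and is ignored here).
#' @return Tibble `sample_id`, `ko`, `abundance` (summed read depth).
#' @export
ko_abundance <- function(contigs, gene_ko) {
  unknown <- setdiff(unique(gene_ko$contig_id), contigs$contig_id)
  if (length(unknown) > 0) {
    abort(sprintf("KO annotation references unknown contig: %s", unknown[1]))
  }
  gene_ko |>
    dplyr::distinct(.data$contig_id, .data$ko) |>
    dplyr::inner_join(
      dplyr::select(contigs, "contig_id", "sample_id", "read_depth"),
      by = "contig_id", relationship = "many-to-many") |>
    dplyr::group_by(.data$sample_id, .data$ko) |>
    dplyr::summarise(abundance = sum(.data$read_depth), .groups = "drop")
}

#' Define a pathway or enzyme as a set of KO terms
#'
#' @param name Pathway/enzyme display name.
#' @param ko_terms Character vector of KO identifiers.
#' @param aggregation `"sum"` (default) or `"mean"` of the member KO
#'   abundances.
#' @return A `pathway_def` list.
#' @export
pathway_def <- function(name, ko_terms, aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.character(name), length(name) == 1, length(ko_terms) > 0)
  structure(list(name = name, ko_terms = ko_terms, aggregation = aggregation),
            class = "pathway_def")
}

#' Read pathway definitions from a YAML file
#'
#' The file is a list of entries with fields `name`, `ko_terms` and optional
#' `aggregation` (sum/mean).
#'
#' @param path Path to YAML file.
#' @return List of [pathway_def()] objects.
#' @export
read_pathway_defs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) {
    pathway_def(p$name, unlist(p$ko_terms), p$aggregation %||% "sum")
  })
}

#' Normalized pathway/enzyme abundance across a metagenome set
#'
#' For each metagenome, the member KO abundances of a pathway are aggregated
#' (sum or mean per definition) and divided by that metagenome's total KO
#' read depth (the sum of read depths of all contigs carrying any KO
#' annotation). The quotient is rescaled by the dataset-wide mean of those
#' per-metagenome totals, so values are comparable across the N metagenomes:
#'
#' \deqn{\frac{\sum_{KO \in P} a_{KO}}{D_s} \times \frac{\sum_s D_s}{N}}
#'
#' where \eqn{a_{KO}} is the per-KO contig read-depth abundance and
#' \eqn{D_s} the per-metagenome KO-bearing contig read-depth total.
#'
#' @param contigs Tibble with `contig_id`, `sample_id`, `read_depth`.
#' @param gene_ko Tibble with `contig_id`, `ko`.
#' @param pathways List of [pathway_def()] objects.
#' @return A wide tibble: `sample_id` plus one column per pathway.
#' @export
pathway_abundance <- function(contigs, gene_ko, pathways) {
  koa <- ko_abundance(contigs, gene_ko)
  # per-sample total read depth of KO-bearing contigs (each contig once)
  rd_cont <- gene_ko |>
    dplyr::distinct(.data$contig_id) |>
    dplyr::inner_join(
      dplyr::select(contigs, "contig_id", "sample_id", "read_depth"),
      by = "contig_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(rd = sum(.data$read_depth), .groups = "drop")
  all_samples <- unique(contigs$sample_id)
  rd_cont <- tibble::tibble(sample_id = all_samples) |>
    dplyr::left_join(rd_cont, by = "sample_id") |>
    dplyr::mutate(rd = dplyr::coalesce(.data$rd, 0))
  if (any(rd_cont$rd == 0)) {
    abort(sprintf("metagenome with zero KO-bearing contig read depth: %s",
                  rd_cont$sample_id[rd_cont$rd == 0][1]))
  }
  n <- length(all_samples)
  mean_rd <- sum(rd_cont$rd) / n

  cols <- lapply(pathways, function(p) {
    member <- koa |>
      dplyr::filter(.data$ko %in% p$ko_terms) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        agg = if (p$aggregation == "sum") sum(.data$abundance)
              else mean(.data$abundance),
        .groups = "drop")
    rd_cont |>
      dplyr::left_join(member, by = "sample_id") |>
      dplyr::mutate(value = dplyr::coalesce(.data$agg, 0) / .data$rd * mean_rd) |>
      dplyr::pull(.data$value)
  })
  out <- tibble::tibble(sample_id = rd_cont$sample_id)
  for (i in seq_along(pathways)) out[[pathways[[i]]$name]] <- cols[[i]]
  out
}

# Local alignment score with the classic parameterization: match +2,
# mismatch -1, gap open -0.5 (charged on the first gap position), gap
# extend -0.1 (each further position). Biostrings charges opening+extension
# on the first gap position, hence the 0.4/0.1 translation.
local_align_score <- function(a, b, match = 2, mismatch = -1,
                              gap_open = -0.5, gap_extend = -0.1) {
  alpha <- Biostrings::AA_ALPHABET
  sm <- matrix(mismatch, length(alpha), length(alpha),
               dimnames = list(alpha, alpha))
  diag(sm) <- match
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm, type = "local",
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend,
    scoreOnly = TRUE)
}

#' Assign a functional role to a protein by parameterized local alignment
#'
#' Enzymes catalysing redox reactions or reactions shared by homologous
#' families (e.g. ammonia vs. methane monooxygenase) cannot be resolved by a
#' KO term alone. The query protein is locally aligned (match +2, mismatch
#' -1, gap open -0.5, gap extend -0.1, score only) against a library of
#' reference proteins with known roles; the role of the highest-scoring
#' reference wins. Score ties across roles return the lexicographically
#' first role with `tie = TRUE`.
#'
#' @param query Amino-acid sequence (single string).
#' @param library Tibble with columns `role`, `sequence`.
#' @return A one-row tibble: `role`, `score`, `tie`.
#' @export
assign_role <- function(query, library) {
  if (nrow(library) == 0) abort("empty role library")
  stopifnot(nzchar(query), all(nzchar(library$sequence)))
  scores <- vapply(library$sequence, function(ref) local_align_score(query, ref),
                   numeric(1), USE.NAMES = FALSE)
  best <- max(scores)
  roles <- sort(unique(library$role[scores == best]))
  tibble::tibble(role = roles[1], score = best, tie = length(roles) > 1)
}
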