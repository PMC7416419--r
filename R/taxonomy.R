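#' Assign contig taxonomy by gene-lineage voting
#'
#' Each contig is classified from the taxonomic lineages of its predicted
#' genes:
#'
#' * (a) at least 30\% of the genes on the contig (all predicted genes, with
#'   or without a lineage) must carry a taxonomic assignment, otherwise the
#'   contig is unassigned; the threshold is inclusive.
#' * (b) the contig takes the taxon held by the most genes. The vote is
#'   hierarchical, starting at species and moving up one rank at a time: a
#'   rank wins when a single taxon is held by at least two genes and by more
#'   genes than any other taxon at that rank. Ties escalate to the next
#'   higher rank.
#' * (c) if no rank up to domain produces a unique winner (e.g. every
#'   assigned gene has a distinct lineage at every rank) the contig is
#'   unassigned. A contig with zero genes is unassigned.
#'
#' A single assigned gene, when it is the only assigned gene on a qualifying
#' contig, wins unopposed at its own lowest rank.
#'
#' @param contigs Tibble with at least `contig_id` (and any other columns,
#'   carried through). Contigs absent from `genes` are treated as having zero
#'   genes.
#' @param genes Tibble with columns `contig_id` and `lineage` (normalized
#'   lineage string, `NA` for genes without taxonomic assignment).
#' @param min_assigned_frac Rule (a) threshold, default 0.3 (inclusive).
#' @return A tibble with one row per contig: `contig_id`, `lineage` (`NA` if
#'   unassigned), `rank` (`"unassigned"` or a rank name), `vote_fraction`
#'   (winning-taxon share of the assigned genes; `NA` if unassigned),
#'   `n_genes`, `n_assigned`.
#' @export
assign_contig_taxonomy <- function(contigs, genes, min_assigned_frac = 0.3) {
  stopifnot(all(c("contig_id") %in% names(contigs)),
            all(c("contig_id", "lineage") %in% names(genes)))

  by_contig <- split(genes$lineage, genes$contig_id)
  ids <- contigs$contig_id
  res <- lapply(ids, function(cid) {
    vote_contig(by_contig[[cid]] %||% character(0), min_assigned_frac)
  })
  tibble::tibble(
    contig_id = ids,
    lineage = vapply(res, `[[`, character(1), "lineage"),
    rank = vapply(res, `[[`, character(1), "rank"),
    vote_fraction = vapply(res, `[[`, numeric(1), "vote_fraction"),
    n_genes = vapply(res, `[[`, integer(1), "n_genes"),
    n_assigned = vapply(res, `[[`, integer(1), "n_assigned")
  )
}

# Vote on one contig's gene lineages. `lineages` includes NA entries for
# genes without assignment; the 30% rule denominator is all of them.
vote_contig <- function(lineages, min_assigned_frac = 0.3) {
  n_genes <- length(lineages)
  assigned <- lineages[!is.na(lineages)]
  n_assigned <- length(assigned)
  unassigned <- list(lineage = NA_character_, rank = "unassigned",
                     vote_fraction = NA_real_,
                     n_genes = n_genes, n_assigned = n_assigned)
  if (n_genes == 0L || n_assigned / n_genes < min_assigned_frac) {
    return(unassigned)
  }
  if (n_assigned == 1L) {
    return(list(lineage = assigned, rank = lowest_rank(assigned),
                vote_fraction = 1, n_genes = n_genes, n_assigned = n_assigned))
  }
  # fast path: unanimous lineages
  if (length(unique(assigned)) == 1L) {
    return(list(lineage = assigned[1], rank = lowest_rank(assigned[1]),
                vote_fraction = 1, n_genes = n_genes, n_assigned = n_assigned))
  }
  depths <- lineage_depth(assigned)
  for (d in seq(7L, 1L)) {
    voters <- assigned[depths >= d]
    if (length(voters) == 0L) next
    labels <- lineage_prefix(voters, d)
    tab <- table(labels)
    m <- max(tab)
    if (m >= 2L && sum(tab == m) == 1L) {
      winner <- names(tab)[which.max(tab)]
      return(list(lineage = winner, rank = tax_ranks()[d],
                  vote_fraction = as.numeric(m) / n_assigned,
                  n_genes = n_genes, n_assigned = n_assigned))
    }
  }
  unassigned
}

#' Bin classified contigs into OTUs at the lowest available rank
#'
#' One OTU bin per distinct (winning lineage, rank). The OTU name is the
#' taxon label at the assigned rank; alphanumeric labels (containing digits)
#' get a higher-rank context prefix for readability. Unassigned contigs form
#' a reserved pool and never become an OTU. The functional subset excludes
#' contigs with two or fewer predicted genes, which carry too little signal
#' for functional inference.
#'
#' @param assignments Output of [assign_contig_taxonomy()].
#' @param min_genes_for_function Contigs with strictly fewer genes than this
#'   are excluded from the functional subset (default 3, i.e. contigs with
#'   <= 2 genes are dropped).
#' @return A tibble with one row per assigned contig: `contig_id`,
#'   `otu_name`, `rank`, `lineage`, `domain`, `functional` (logical). The
#'   unassigned contig ids are attached as attribute `"unassigned_pool"`.
#' @export
bin_otus <- function(assignments, min_genes_for_function = 3L) {
  assigned <- dplyr::filter(assignments, !is.na(.data$lineage))
  pool <- assignments$contig_id[is.na(assignments$lineage)]
  if (nrow(assigned) == 0) {
    out <- tibble::tibble(contig_id = character(), otu_name = character(),
                          rank = character(), lineage = character(),
                          domain = character(), functional = logical())
    attr(out, "unassigned_pool") <- pool
    return(out)
  }
  out <- assigned |>
    dplyr::mutate(
      otu_name = otu_display_name(.data$lineage),
      domain = lineage_domain(.data$lineage),
      functional = .data$n_genes >= min_genes_for_function
    ) |>
    dplyr::select("contig_id", "otu_name", "rank", "lineage", "domain",
                  "functional")
  attr(out, "unassigned_pool") <- pool
  out
}

# Label at the lowest rank; alphanumeric labels are prefixed with the
# closest purely alphabetic higher-rank label for context.
otu_display_name <- function(lineage) {
  vapply(lineage, function(l) {
    f <- lineage_fields(l)
    lab <- f[length(f)]
    if (grepl("[0-9]", lab) && length(f) > 1) {
      ctx <- rev(f[-length(f)])
      ctx <- ctx[!grepl("[0-9]", ctx)]
      if (length(ctx) > 0) lab <- paste(ctx[1], lab)
    }
    lab
  }, character(1), USE.NAMES = FALSE)
}
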