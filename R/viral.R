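#' Viral cluster abundance per time period
#'
#' The read depths of a cluster's member contigs are summed over all samples
#' collected in each time period (calendar month of sampling, e.g.
#' "Dec. 2006"). A cluster is abundant when its total read depth exceeds the
#' threshold (strictly) in at least one period; the default of 4000
#' corresponds to a fixed fraction of the peak read depth of the dominant
#' interface phototroph and is data-dependent, hence configurable.
#'
#' @param clusters Tibble with `cluster_id`, `contig_id` (cluster membership;
#'   singletons are clusters of one).
#' @param contigs Tibble with `contig_id`, `sample_id`, `read_depth`.
#' @param meta Tibble with `sample_id`, `date`.
#' @param threshold Strict abundance threshold on per-period total read
#'   depth, default 4000.
#' @return A list with `per_period` (tibble `cluster_id`, `period`,
#'   `total_read_depth`) covering every cluster x sampled period (0 when
#'   absent), and `abundant` (tibble `cluster_id`, `abundant`).
#' @export
cluster_period_abundance <- function(clusters, contigs, meta,
                                     threshold = 4000) {
  periods <- meta |>
    dplyr::mutate(period = period_label(.data$date)) |>
    dplyr::select("sample_id", "period")
  depth <- clusters |>
    dplyr::inner_join(
      dplyr::select(contigs, "contig_id", "sample_id", "read_depth"),
      by = "contig_id", relationship = "many-to-many") |>
    dplyr::inner_join(periods, by = "sample_id") |>
    dplyr::group_by(.data$cluster_id, .data$period) |>
    dplyr::summarise(total_read_depth = sum(.data$read_depth),
                     .groups = "drop")
  grid <- tidyr::expand_grid(cluster_id = unique(clusters$cluster_id),
                             period = unique(periods$period))
  per_period <- grid |>
    dplyr::left_join(depth, by = c("cluster_id", "period")) |>
    dplyr::mutate(total_read_depth =
                    dplyr::coalesce(.data$total_read_depth, 0))
  abundant <- per_period |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(abundant = any(.data$total_read_depth > threshold),
                     .groups = "drop")
  list(per_period = per_period, abundant = abundant)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Match CRISPR spacers against contigs
#'
#' Ungapped, seeded alignment emulating short-sequence megablast at desk
#' scale: exact k-mer seeds (disjoint windows of the spacer, default k = 12)
#' locate candidate positions on either strand; each candidate is extended
#' to the full spacer length (clipped at contig ends) and scored as
#' matches / aligned length. Hits pass when identity and the aligned
#' fraction of the spacer both reach their thresholds. Target coordinates
#' are 0-based half-open on the forward strand.
#'
#' @param spacers Named character vector of spacer sequences (20--60 bp).
#' @param contigs Named character vector of contig sequences.
#' @param min_identity Percent identity cut-off, default 97 (inclusive).
#' @param min_fraction Minimum aligned fraction of the spacer, default 0.97.
#' @param seed_k Exact-match seed length, default 12; spacers shorter than
#'   this are an error.
#' @return Tibble with `spacer_id`, `target_contig`, `identity_pct`,
#'   `alignment_fraction`, `start`, `end`, `strand`.
#' @export
match_spacers <- function(spacers, contigs, min_identity = 97.0,
                          min_fraction = 0.97, seed_k = 12L) {
  if (any(nchar(spacers) < seed_k)) {
    abort(sprintf("spacer shorter than seed length %d", seed_k))
  }
  hits <- list()
  for (sp_id in names(spacers)) {
    sp <- spacers[[sp_id]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") sp else revcomp(sp)
      L <- nchar(q)
      seed_starts <- unique(c(seq(1L, L - seed_k + 1L, by = seed_k),
                              L - seed_k + 1L))
      for (ct_id in names(contigs)) {
        ct <- contigs[[ct_id]]
        cand <- integer(0)
        for (s0 in seed_starts) {
          seed <- substr(q, s0, s0 + seed_k - 1L)
          pos <- gregexpr(seed, ct, fixed = TRUE)[[1]]
          if (pos[1] == -1L) next
          # implied spacer start position on the contig (1-based)
          cand <- c(cand, as.integer(pos) - s0 + 1L)
        }
        for (a in unique(cand)) {
          t1 <- max(1L, a)
          t2 <- min(nchar(ct), a + L - 1L)
          q1 <- t1 - a + 1L
          q2 <- t2 - a + 1L
          aln_len <- t2 - t1 + 1L
          if (aln_len <= 0) next
          qs <- strsplit(substr(q, q1, q2), "", fixed = TRUE)[[1]]
          ts <- strsplit(substr(ct, t1, t2), "", fixed = TRUE)[[1]]
          ident <- sum(qs == ts) / aln_len * 100
          frac <- aln_len / L
          if (ident >= min_identity && frac >= min_fraction) {
            hits[[length(hits) + 1]] <- tibble::tibble(
              spacer_id = sp_id, target_contig = ct_id,
              identity_pct = ident, alignment_fraction = frac,
              start = t1 - 1L, end = t2, strand = strand)
          }
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(spacer_id = character(), target_contig = character(),
                          identity_pct = numeric(),
                          alignment_fraction = numeric(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  dplyr::distinct(dplyr::bind_rows(hits))
}

# Gapped local alignment (match 2 / mismatch -1 / gap -1.5 per position)
# returning identity over aligned columns and aligned fraction of `query`.
align_identity <- function(query, subject) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                 baseOnly = FALSE)
  best <- NULL
  for (q in c(query, revcomp(query))) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(subject),
      substitutionMatrix = sm, type = "local",
      gapOpening = 0, gapExtension = 1.5)
    cols <- Biostrings::nchar(al)  # aligned columns incl. gaps
    ident <- if (cols > 0) Biostrings::nmatch(al) / cols * 100 else 0
    cand <- list(identity = ident, fraction = cols / nchar(query),
                 score = Biostrings::score(al))
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

#' Expand a viral cluster by sequence similarity
#'
#' Candidate contigs whose best gapped local alignment to any current member
#' reaches both the identity and the alignment-fraction threshold are added
#' to the cluster. Different clusters warrant different identity thresholds
#' (tight ones for well-sampled clusters, looser for divergent ones); the
#' default is the 90 percent cut-off used for cluster-wide expansion.
#' The operation is idempotent on a fixed candidate set.
#'
#' @param members Named character vector of current member sequences.
#' @param candidates Named character vector of candidate contig sequences.
#' @param min_identity Percent identity threshold (default 90, inclusive).
#' @param min_fraction Minimum aligned fraction of the candidate (default
#'   0.98).
#' @return Named character vector: members plus admitted candidates.
#' @export
expand_cluster <- function(members, candidates, min_identity = 90,
                           min_fraction = 0.98) {
  new <- members
  for (cid in setdiff(names(candidates), names(members))) {
    cand <- candidates[[cid]]
    for (m in members) {
      al <- align_identity(cand, m)
      if (al$identity >= min_identity && al$fraction >= min_fraction) {
        new[cid] <- cand
        break
      }
    }
  }
  new
}

#' Assign putative hosts to viral clusters from spacer hits
#'
#' A cluster's candidate hosts are the taxa owning the CRISPR arrays whose
#' spacers hit any member contig. All hosts are reported, unranked: a
#' cluster hit by spacers from two taxa gets both.
#'
#' @param hits Spacer hits from [match_spacers()].
#' @param spacer_origin Tibble with `spacer_id`, `host_taxon` (the taxon of
#'   the CRISPR array each spacer came from).
#' @param clusters Tibble with `cluster_id`, `contig_id`.
#' @return Tibble `cluster_id`, `host_taxon`, `n_spacers`, one row per
#'   (cluster, host); clusters with no hits are absent.
#' @export
assign_hosts <- function(hits, spacer_origin, clusters) {
  hits |>
    dplyr::inner_join(clusters, by = c(target_contig = "contig_id"),
                      relationship = "many-to-many") |>
    dplyr::inner_join(spacer_origin, by = "spacer_id") |>
    dplyr::group_by(.data$cluster_id, .data$host_taxon) |>
    dplyr::summarise(n_spacers = dplyr::n_distinct(.data$spacer_id),
                     .groups = "drop")
}

#' Pearson correlation between host marker depth and virus cluster depth
#'
#' @param host_series Numeric vector (e.g. average marker-gene read depth
#'   per sample).
#' @param virus_series Numeric vector of matching length (cluster total read
#'   depth per sample).
#' @return Tibble `r`, `p`, `n` (two-sided p from the t distribution on
#'   n - 2 df).
#' @export
host_virus_correlation <- function(host_series, virus_series) {
  stopifnot(length(host_series) == length(virus_series))
  ok <- stats::complete.cases(host_series, virus_series)
  x <- host_series[ok]; y <- virus_series[ok]
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in a series")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
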