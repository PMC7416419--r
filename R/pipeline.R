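#' Pipeline configuration
#'
#' Bundles the scenario, output directory and the analysis thresholds with
#' their standard defaults: abundant OTUs at >= 1% relative abundance,
#' viral clusters at per-period total read depth > 4000, spacer matching at
#' >= 97% identity, cluster expansion at >= 90% identity.
#'
#' @param out_dir Output directory.
#' @param scenario A [lake_scenario()]; default [default_lake_scenario()].
#' @param abundant_threshold Percent relative abundance for abundant OTUs.
#' @param viral_threshold Per-period read-depth threshold for abundant
#'   clusters (strict).
#' @param spacer_min_identity,spacer_min_fraction Spacer-hit gates.
#' @param expansion_min_identity,expansion_min_fraction Cluster-expansion
#'   gates.
#' @param spacer_mutation_rate Mutation rate used when planting spacers.
#' @param pathways List of [pathway_def()]; default one definition per KO
#'   repertoire theme of the default scenario.
#' @param seed Overrides the scenario seed when given.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            scenario = default_lake_scenario(),
                            abundant_threshold = 1.0,
                            viral_threshold = 4000,
                            spacer_min_identity = 97.0,
                            spacer_min_fraction = 0.97,
                            expansion_min_identity = 90,
                            expansion_min_fraction = 0.98,
                            spacer_mutation_rate = 0,
                            pathways = default_pathways(),
                            seed = NULL) {
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir, scenario = scenario,
    abundant_threshold = abundant_threshold,
    viral_threshold = viral_threshold,
    spacer_min_identity = spacer_min_identity,
    spacer_min_fraction = spacer_min_fraction,
    expansion_min_identity = expansion_min_identity,
    expansion_min_fraction = expansion_min_fraction,
    spacer_mutation_rate = spacer_mutation_rate,
    pathways = pathways
  ), class = "pipeline_config")
}

#' Default pathway definitions for the synthetic community
#'
#' Small KO sets standing in for energy-conservation pathways of the
#' stratified community: anoxygenic photosynthesis / sulfur oxidation
#' (interface phototroph), oxygenic photosynthesis and carbon fixation
#' (upper-zone phototrophs), dissimilatory sulfate reduction and
#' methanogenesis (lower-zone anaerobes).
#'
#' @return List of [pathway_def()] objects.
#' @export
default_pathways <- function() {
  list(
    pathway_def("Sulfur oxidation (GSB)", c("K11180", "K11181", "K08928")),
    pathway_def("Oxygenic photosynthesis", c("K02703", "K02706")),
    pathway_def("Carbon fixation", c("K01601", "K01595", "K00855")),
    pathway_def("Sulfate reduction", c("K00394", "K00399"),
                aggregation = "mean"),
    pathway_def("Fermentation", c("K00925", "K00625"))
  )
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Stages: simulate, classify contigs, abundance accounting, KEGG profile,
#' viral linkage, ecology statistics. Every stage's table is written as TSV
#' under `config$out_dir` and a manifest records per-stage row counts and
#' file checksums; a rerun with the same configuration and seed is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print one progress line per stage.
#' @return Invisibly, a list with the stage results and the `manifest`
#'   tibble.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  outputs <- character(0)
  put <- function(x, name) {
    path <- file.path(config$out_dir, name)
    write_result_table(x, path)
    outputs[[name]] <<- path
    path
  }

  say("stage simulate: seed %d", config$scenario$seed)
  sim <- stage("simulate", simulate_lake(config$scenario))
  put(sim$samples |> dplyr::mutate(date = format(.data$date)), "samples.tsv")
  put(sim$contigs, "contigs.tsv")
  put(sim$truth, "ground_truth.tsv")
  say("stage simulate: %d samples, %d contigs, %d genes",
      nrow(sim$samples), nrow(sim$contigs), nrow(sim$genes))

  say("stage classify-contigs")
  assignments <- stage("classify-contigs",
                       assign_contig_taxonomy(sim$contigs, sim$genes))
  bins <- stage("classify-contigs", bin_otus(assignments))
  put(assignments, "assignments.tsv")

  say("stage abundance")
  ra <- stage("abundance", relative_abundance(sim$contigs, bins))
  abundant <- stage("abundance",
                    select_abundant(ra, sim$contigs, bins,
                                    threshold = config$abundant_threshold))
  domains <- dplyr::distinct(bins, .data$otu_name, .data$domain)
  grouped <- stage("abundance", group_other(ra, abundant, domains))
  put(ra, "abundance.tsv")
  put(grouped, "abundance_grouped.tsv")

  say("stage kegg-profile")
  # virion-fraction metagenomes carry no KO-annotated cellular contigs in
  # this design; the functional profile is over the cellular fractions
  cellular <- sim$samples$sample_id[sim$samples$filter_fraction_um != 0.1]
  pa <- stage("kegg-profile", pathway_abundance(
    dplyr::filter(sim$contigs, .data$sample_id %in% cellular),
    sim$gene_ko, config$pathways))
  put(pa, "pathways.tsv")

  say("stage viral")
  planted <- stage("viral",
                   plant_spacers(sim, mutation_rate = config$spacer_mutation_rate))
  cpa <- stage("viral",
               cluster_period_abundance(sim$clusters, sim$contigs, sim$samples,
                                        threshold = config$viral_threshold))
  hits <- stage("viral",
                match_spacers(planted$spacers, sim$virus_seqs,
                              min_identity = config$spacer_min_identity,
                              min_fraction = config$spacer_min_fraction))
  spacer_origin <- dplyr::select(planted$truth, "spacer_id", "host_taxon")
  hosts <- stage("viral", assign_hosts(hits, spacer_origin, sim$clusters))
  put(cpa$per_period, "viral_cluster_abundance.tsv")
  put(hits, "spacer_hits.tsv")
  put(hosts, "host_assignments.tsv")

  say("stage ecology")
  ra_cell <- dplyr::filter(grouped, .data$sample_id %in% cellular)
  div <- stage("ecology", simpson_diversity(grouped))
  res <- stage("ecology", bray_curtis(ra_cell))
  groups <- sim$samples |>
    dplyr::filter(.data$sample_id %in% cellular) |>
    dplyr::transmute(.data$sample_id, group = .data$season)
  smp <- stage("ecology", simper_contrib(ra_cell, groups))
  env <- env_normalize(sim$samples)
  ord <- stage("ecology",
               dbrda_fit(res, dplyr::filter(env, .data$sample_id %in% cellular),
                         selection = "forward"))
  put(div, "simpson_diversity.tsv")
  put(tidy(res), "resemblance.tsv")
  put(smp$within, "simper_within.tsv")
  put(smp$between, "simper_between.tsv")
  put(ord$scores, "dbrda_scores.tsv")
  put(ord$axes, "dbrda_axes.tsv")

  manifest <- tibble::tibble(
    file = names(outputs),
    rows = vapply(outputs, function(p) length(readLines(p)) - 1L, integer(1)),
    md5 = unname(tools::md5sum(unlist(outputs))),
    seed = config$scenario$seed
  )
  write_result_table(manifest, file.path(config$out_dir, "manifest.tsv"))
  say("done: %d output files", nrow(manifest))

  invisible(list(sim = sim, assignments = assignments, bins = bins,
                 abundance = ra, abundance_grouped = grouped,
                 abundant = abundant, pathways = pa,
                 viral = cpa, spacer_hits = hits, hosts = hosts,
                 diversity = div, resemblance = res, simper = smp,
                 ordination = ord, manifest = manifest))
}
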