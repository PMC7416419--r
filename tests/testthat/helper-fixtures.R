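# Small scenario builders shared across test files.

# Two cellular OTUs on a reduced design; fast enough for Monte-Carlo loops.
tiny_scenario <- function(seed = 1, noise_sd = 0.1,
                          taxon_assignment_rate = 1,
                          with_virus = TRUE, coupling = 0.9) {
  profs <- list(
    otu_profile("PhotoA",
                "Bacteria;Chlorobi;Chlorobia;Chlorobiales;Chlorobiaceae;Chlorobium",
                depth_niche = c("U1", "I"),
                season_response = c(summer = 60, winter = 6, spring = 1),
                contig_count_range = c(5L, 8L),
                taxon_assignment_rate = taxon_assignment_rate,
                ko_repertoire = c("K11180", "K11181")),
    otu_profile("HeteroB",
                "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Flavobacterium",
                depth_niche = c("U1", "I"),
                season_response = c(summer = 20, winter = 30, spring = 30),
                contig_count_range = c(5L, 8L),
                taxon_assignment_rate = taxon_assignment_rate,
                ko_repertoire = c("K01183"))
  )
  viruses <- if (with_virus) {
    list(virus_profile("VirA", host_otu = "PhotoA", coupling = coupling,
                       genome_length_bp = 4000L, n_contigs = 2L,
                       base_share = 10))
  } else list()
  lake_scenario(
    profs, viruses,
    dates = as.Date(c("2013-12-15", "2014-02-10", "2014-07-20",
                      "2014-10-10")),
    depths = c("U1", "I"), fractions = c(3.0, 0.1),
    noise_sd = noise_sd, background_contigs = 10L,
    total_coverage = 2e6, seed = seed)
}

make_lineage <- function(...) paste(c(...), collapse = ";")
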