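test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_lake(tiny_scenario(seed = 5))
  s2 <- simulate_lake(tiny_scenario(seed = 5))
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$virus_seqs, s2$virus_seqs)

  s3 <- simulate_lake(tiny_scenario(seed = 6))
  expect_false(identical(s1$contigs, s3$contigs))
})

test_that("coverage shares conserve the 100% budget before noise", {
  sim <- simulate_lake(tiny_scenario(seed = 2, noise_sd = 0))
  shares <- sim$contigs |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(as.numeric(length_bp) * read_depth))
  expect_equal(shares$total,
               rep(tiny_scenario()$total_coverage, nrow(shares)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # truth rows also sum to 100
  tsum <- sim$truth |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(true_ra))
  expect_equal(tsum$s, rep(100, nrow(tsum)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a single-OTU noise-free sample recovers 100% through the pipeline", {
  sc <- lake_scenario(
    list(otu_profile("Only",
                     "Bacteria;Chlorobi;Chlorobia;Chlorobiales;Chlorobiaceae;Chlorobium",
                     depth_niche = "I",
                     season_response = c(summer = 100, winter = 100,
                                         spring = 100),
                     taxon_assignment_rate = 1)),
    dates = as.Date("2014-12-15"), depths = "I", fractions = 3.0,
    noise_sd = 0, background_contigs = 0L, seed = 3)
  sim <- simulate_lake(sc)
  expect_true(all(!is.na(sim$genes$lineage)))
  bins <- bin_otus(assign_contig_taxonomy(sim$contigs, sim$genes))
  ra <- relative_abundance(sim$contigs, bins)
  expect_equal(ra$Chlorobium, 100)
})

test_that("noise-free synthetic output is recovered exactly at the OTU rank", {
  sim <- simulate_lake(tiny_scenario(seed = 4, noise_sd = 0,
                                     taxon_assignment_rate = 1))
  bins <- bin_otus(assign_contig_taxonomy(sim$contigs, sim$genes))
  ra <- relative_abundance(sim$contigs, bins)
  long <- tidyr::pivot_longer(ra, -sample_id, names_to = "otu_name",
                              values_to = "ra")
  merged <- dplyr::inner_join(sim$truth, long,
                              by = c("sample_id", "otu_name"))
  # every truth entry is matched and equal
  expect_equal(nrow(merged), nrow(sim$truth))
  expect_equal(merged$ra, merged$true_ra, tolerance = 1e-9)
})

test_that("expected abundances are seed-independent (Monte-Carlo)", {
  # same scenario under many seeds: mean recovered abundance approaches the
  # target within 3 standard errors
  reps <- 20
  got <- vapply(seq_len(reps), function(s) {
    sim <- simulate_lake(tiny_scenario(seed = 100 + s, noise_sd = 0.1))
    bins <- bin_otus(assign_contig_taxonomy(sim$contigs, sim$genes))
    ra <- relative_abundance(sim$contigs, bins)
    summer_I <- sim$samples$sample_id[sim$samples$season == "summer" &
                                        sim$samples$depth_code == "I" &
                                        sim$samples$filter_fraction_um == 3.0]
    mean(ra$Chlorobium[ra$sample_id %in% summer_I])
  }, numeric(1))
  target <- 60  # PhotoA summer response in the tiny scenario
  se <- sd(got) / sqrt(reps)
  expect_lt(abs(mean(got) - target), 3 * se + 0.5)
})

test_that("virus contigs partition exclusively into the 0.1 um fraction", {
  sim <- simulate_lake(tiny_scenario(seed = 8))
  frac <- sim$samples$filter_fraction_um[match(sim$contigs$sample_id,
                                               sim$samples$sample_id)]
  is_virus <- sim$contigs$contig_id %in% sim$clusters$contig_id
  expect_true(all(frac[is_virus] == 0.1))
  # cellular OTU contigs never appear in the virion fraction
  cellular <- !is_virus & !grepl("_bg_", sim$contigs$contig_id)
  expect_true(all(frac[cellular] != 0.1))
})

test_that("winter gap removes lower-zone samples from the full design", {
  sim <- simulate_lake(default_lake_scenario(seed = 1, n_dates = 4))
  winter_lower <- sim$samples |>
    dplyr::filter(season == "winter", depth_code %in% c("L1", "L2", "L3"))
  expect_equal(nrow(winter_lower), 0)
  expect_gt(nrow(dplyr::filter(sim$samples, season == "winter")), 0)
})

test_that("over-committed scenarios are rejected at construction", {
  expect_error(lake_scenario(
    list(otu_profile("A", "Bacteria;Chlorobi", "I",
                     c(summer = 70, winter = 10, spring = 10)),
         otu_profile("B", "Bacteria;Cyanobacteria", "I",
                     c(summer = 40, winter = 10, spring = 10))),
    dates = as.Date("2014-12-15"), depths = "I", fractions = 3.0),
    "sum to 110.0% > 100%")
})

test_that("planted spacers match their source perfectly at mutation rate 0", {
  sim <- simulate_lake(tiny_scenario(seed = 9))
  pl <- plant_spacers(sim, mutation_rate = 0)
  expect_true(all(pl$truth$identity_pct == 100))
  # every spacer is an exact substring of its recorded source contig
  for (i in seq_len(nrow(pl$truth))) {
    src <- sim$virus_seqs[[pl$truth$source_contig[i]]]
    expect_identical(substr(src, pl$truth$start[i] + 1,
                            pl$truth$start[i] + 32),
                     unname(pl$spacers[pl$truth$spacer_id[i]]))
  }
})

test_that("spacer mutation load matches the binomial expectation", {
  sim <- simulate_lake(tiny_scenario(seed = 10))
  rate <- 0.05
  muts <- unlist(lapply(1:20, function(r) {
    plant_spacers(sim, mutation_rate = rate, n_per_virus = 10,
                  seed = 1000 + r)$truth$n_mutations
  }))
  # binomial expectation: mean identity = 100 * (1 - rate) = 95%, below
  # the 97% gate; even a single mutation (31/32 = 96.9%) fails it
  expected <- 32 * rate
  se <- sqrt(32 * rate * (1 - rate) / length(muts))
  expect_lt(abs(mean(muts) - expected), 4 * se)
  mean_identity <- mean((32 - muts) / 32 * 100)
  expect_lt(abs(mean_identity - 95), 4 * se / 32 * 100)
})

test_that("spacers never hit an unrelated virus sharing no 20-mer", {
  sim <- simulate_lake(tiny_scenario(seed = 12))
  pl <- plant_spacers(sim, mutation_rate = 0)
  hits <- match_spacers(pl$spacers, sim$virus_seqs)
  joined <- dplyr::inner_join(hits, sim$clusters,
                              by = c(target_contig = "contig_id"))
  truth_cluster <- pl$truth$cluster_id[match(joined$spacer_id,
                                             pl$truth$spacer_id)]
  # brute-force guard: the genomes share no 20-mer, so any cross-cluster
  # hit would be a matcher defect
  kmers <- function(s, k = 20) {
    vapply(seq_len(nchar(s) - k + 1), function(i) substr(s, i, i + k - 1), "")
  }
  by_cluster <- split(sim$virus_seqs[sim$clusters$contig_id],
                      sim$clusters$cluster_id)
  if (length(by_cluster) > 1) {
    sets <- lapply(by_cluster, function(ss) unique(unlist(lapply(ss, kmers))))
    expect_length(intersect(sets[[1]], sets[[2]]), 0)
  }
  expect_true(all(joined$cluster_id == truth_cluster))
})

test_that("spacer length longer than the virus contigs is rejected", {
  sim <- simulate_lake(tiny_scenario(seed = 13))
  expect_error(plant_spacers(sim, spacer_length = 10000L),
               "exceeds")
})
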