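#' Define an OTU profile for the synthetic lake
#'
#' Describes one community member: its lineage, the depths it occupies, its
#' target relative abundance per season, and how its contigs and genes are
#' drawn.
#'
#' @param name OTU display name (informational; the pipeline re-derives
#'   names from lineages).
#' @param lineage Normalized lineage string.
#' @param depth_niche Character subset of [depth_codes()].
#' @param season_response Named numeric: target relative abundance (%) for
#'   `summer`, `winter`, `spring`.
#' @param fractions Filter fractions (um) this member partitions into;
#'   cellular members default to the 3.0 and 0.8 um fractions.
#' @param contig_count_range Integer interval for contigs per sample.
#' @param contig_length_meanlog,contig_length_sdlog Log-normal parameters of
#'   contig length in log-bp.
#' @param gene_density Predicted genes per kbp.
#' @param taxon_assignment_rate Probability a gene carries the OTU lineage.
#' @param ko_repertoire Character vector of KO terms genes may carry.
#' @param ko_rate Probability a gene carries a KO term.
#' @return An `otu_profile` list.
#' @export
otu_profile <- function(name, lineage, depth_niche, season_response,
                        fractions = c(3.0, 0.8),
                        contig_count_range = c(6L, 12L),
                        contig_length_meanlog = log(2000),
                        contig_length_sdlog = 0.45,
                        gene_density = 1.0,
                        taxon_assignment_rate = 0.7,
                        ko_repertoire = character(),
                        ko_rate = 0.5) {
  stopifnot(all(depth_niche %in% depth_codes()),
            all(c("summer", "winter", "spring") %in% names(season_response)),
            all(season_response >= 0),
            taxon_assignment_rate >= 0, taxon_assignment_rate <= 1)
  structure(list(
    name = name, lineage = parse_lineage(lineage), depth_niche = depth_niche,
    season_response = season_response, fractions = fractions,
    contig_count_range = as.integer(contig_count_range),
    contig_length_meanlog = contig_length_meanlog,
    contig_length_sdlog = contig_length_sdlog,
    gene_density = gene_density,
    taxon_assignment_rate = taxon_assignment_rate,
    ko_repertoire = ko_repertoire, ko_rate = ko_rate
  ), class = "otu_profile")
}

#' Define a virus profile for the synthetic lake
#'
#' Virus genomes are emitted as contig groups (clusters when 2+ contigs,
#' singletons otherwise), partitioned exclusively into the 0.1 um virion
#' fraction. The per-sample coverage share of the cluster is coupled to the
#' host's abundance trajectory with a target Pearson correlation.
#'
#' @param name Virus/cluster name.
#' @param host_otu Name of the host OTU profile.
#' @param coupling Target Pearson correlation with host abundance, in
#'   [-1, 1].
#' @param genome_length_bp Genome length (bp).
#' @param n_contigs Number of assembled contigs representing the genome.
#' @param base_share Mean coverage share (%) in the 0.1 um fraction.
#' @param spacer_donor Does the host's CRISPR array carry spacers from this
#'   genome?
#' @return A `virus_profile` list.
#' @export
virus_profile <- function(name, host_otu, coupling, genome_length_bp = 12000L,
                          n_contigs = 3L, base_share = 8,
                          spacer_donor = TRUE) {
  stopifnot(coupling >= -1, coupling <= 1, genome_length_bp >= 500)
  structure(list(name = name, host_otu = host_otu, coupling = coupling,
                 genome_length_bp = as.integer(genome_length_bp),
                 n_contigs = as.integer(n_contigs), base_share = base_share,
                 spacer_donor = spacer_donor),
            class = "virus_profile")
}

#' Assemble a synthetic lake scenario
#'
#' @param otu_profiles List of [otu_profile()] objects.
#' @param virus_profiles List of [virus_profile()] objects.
#' @param dates Sampling dates (`Date`), each in a sampled month.
#' @param depths Depth codes sampled, default all seven.
#' @param fractions Filter fractions, default 3.0/0.8/0.1 um.
#' @param noise_sd Log-normal sd of multiplicative read-depth noise
#'   (0 = noise-free).
#' @param total_coverage Per-sample total coverage budget.
#' @param background_contigs Contigs of taxonomically unassigned background
#'   per sample.
#' @param winter_gap Drop lower-zone (L1--L3) samples in winter months, as
#'   in the field design.
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @return A `lake_scenario` list.
#' @export
lake_scenario <- function(otu_profiles, virus_profiles = list(),
                          dates, depths = depth_codes(),
                          fractions = filter_fractions(),
                          noise_sd = 0.1, total_coverage = 2e7,
                          background_contigs = 40L, winter_gap = TRUE,
                          seed = 1L) {
  dates <- as.Date(dates)
  lake_season(dates)  # validates months
  otu_names <- vapply(otu_profiles, `[[`, character(1), "name")
  stopifnot(!anyDuplicated(otu_names))
  for (v in virus_profiles) {
    if (!v$host_otu %in% otu_names) {
      abort(sprintf("virus '%s' references unknown host OTU '%s'",
                    v$name, v$host_otu))
    }
  }
  sc <- structure(list(
    otu_profiles = otu_profiles, virus_profiles = virus_profiles,
    dates = dates, depths = depths, fractions = fractions,
    noise_sd = noise_sd, total_coverage = total_coverage,
    background_contigs = as.integer(background_contigs),
    winter_gap = winter_gap, seed = as.integer(seed)
  ), class = "lake_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  seasons <- unique(lake_season(sc$dates))
  for (season in seasons) for (depth in sc$depths) for (fr in sc$fractions) {
    tot <- 0
    for (p in sc$otu_profiles) {
      if (depth %in% p$depth_niche && fr %in% p$fractions) {
        tot <- tot + p$season_response[[season]]
      }
    }
    if (fr == 0.1) {
      tot <- tot + sum(vapply(sc$virus_profiles, `[[`, numeric(1),
                              "base_share"))
    }
    if (tot > 100) {
      abort(sprintf(
        "target abundances sum to %.1f%% > 100%% at (%s, %s, %.1f um)",
        tot, season, depth, fr))
    }
  }
  invisible(sc)
}

# Depth (m) and a smooth seasonal environment model for a high-latitude,
# permanently stratified site: long summer days, short winter days, salinity
# increasing sharply below the oxycline.
depth_m_of <- function(depth_code) {
  c(U1 = 0, U2 = 5, U3 = 12, I = 13.5, L1 = 15, L2 = 18.5, L3 = 23.5)[depth_code]
}

env_of_date <- function(date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  phase <- cos(2 * pi * (doy - 355) / 365.25)    # 1 at austral midsummer
  lagged <- cos(2 * pi * (doy - 385) / 365.25)   # ~1 month thermal lag
  cloud <- cos(4 * pi * (doy - 320) / 365.25)    # semi-annual cloudiness
  tibble::tibble(
    daylength_h = 12 + 9 * phase,
    sunlight_h = pmax(0, (12 + 9 * phase) * 0.45 + 1.2 * cloud),
    air_temp_C = -1 + 9 * lagged
  )
}

salinity_of_depth <- function(depth_m) {
  1.6 + 2.8 / (1 + exp(-(depth_m - 13) / 1.2))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

with_scenario_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a stratified-lake metagenome collection
#'
#' Generates post-assembly annotation tables (contigs with lengths and read
#' depths, gene lineages, gene-KO annotations) for every sample of the
#' scenario's depth x fraction x date design, together with the ground-truth
#' relative abundance of each community member. Read depths are scaled so
#' that each member's coverage share equals its seasonal target, then
#' perturbed by multiplicative log-normal noise; contig lengths are
#' noiseless. Virus contigs are emitted only in the 0.1 um virion fraction,
#' cellular contigs only in the 0.8/3.0 um fractions; winter lower-zone
#' samples are omitted when the scenario has the field design's winter gap.
#'
#' @param scenario A [lake_scenario()].
#' @return A `lake_sim` list: `samples` (metadata tibble), `contigs`,
#'   `genes`, `gene_ko`, `truth` (long tibble `sample_id`, `otu_name`,
#'   `true_ra` covering cellular members and the unassigned remainder),
#'   `virus_truth` (per-sample cluster target shares), `clusters` (cluster
#'   membership), `virus_seqs` (named character vector of virus contig
#'   sequences), and the scenario.
#' @export
simulate_lake <- function(scenario) {
  stopifnot(inherits(scenario, "lake_scenario"))
  with_scenario_seed(scenario$seed, {
    design <- tidyr::expand_grid(
      date = scenario$dates, depth_code = scenario$depths,
      filter_fraction_um = scenario$fractions) |>
      dplyr::mutate(season = lake_season(.data$date))
    if (scenario$winter_gap) {
      design <- dplyr::filter(design, !(.data$season == "winter" &
                                          .data$depth_code %in% c("L1", "L2", "L3")))
    }
    design <- design |>
      dplyr::mutate(sample_id = sprintf(
        "%s_%s_%g", format(.data$date, "%Y%b"), .data$depth_code,
        .data$filter_fraction_um))

    samples <- design |>
      dplyr::mutate(depth_m = depth_m_of(.data$depth_code),
                    salinity_pct = salinity_of_depth(.data$depth_m)) |>
      dplyr::bind_cols(env_of_date(design$date)) |>
      dplyr::select("sample_id", "date", "depth_code", "filter_fraction_um",
                    "season", "depth_m", "salinity_pct", "daylength_h",
                    "sunlight_h", "air_temp_C")

    # --- virus genomes, contigs, and per-sample target shares -------------
    viruses <- simulate_virus_layer(scenario, samples)

    contigs <- list(); genes <- list(); gene_ko <- list(); truth <- list()
    gene_counter <- 0L

    for (si in seq_len(nrow(samples))) {
      sm <- samples[si, ]
      sid <- sm$sample_id
      members <- list()  # name -> list(target, profile or NULL for background)
      for (p in scenario$otu_profiles) {
        if (sm$depth_code %in% p$depth_niche &&
            sm$filter_fraction_um %in% p$fractions) {
          t <- p$season_response[[sm$season]]
          if (t > 0) members[[p$name]] <- list(target = t, profile = p)
        }
      }
      v_share <- 0
      if (nrow(viruses$share) > 0) {
        vs <- dplyr::filter(viruses$share, .data$sample_id == sid)
        v_share <- sum(vs$target)
      }
      cell_share <- sum(vapply(members, `[[`, numeric(1), "target"))
      bg_target <- 100 - cell_share - v_share
      stopifnot(bg_target >= 0)

      # cellular + background contigs
      emit <- function(n, lengths, target, tag) {
        cov_w <- lengths / sum(lengths)
        cov <- target / 100 * scenario$total_coverage * cov_w
        depth <- cov / lengths
        if (scenario$noise_sd > 0) {
          depth <- depth * rlnorm(n, meanlog = 0, sdlog = scenario$noise_sd)
        }
        tibble::tibble(
          contig_id = sprintf("%s_%s_c%03d", sid, tag, seq_len(n)),
          sample_id = sid, length_bp = as.integer(lengths),
          read_depth = depth)
      }

      for (nm in names(members)) {
        p <- members[[nm]]$profile
        rng <- p$contig_count_range
        n <- if (rng[1] == rng[2]) rng[1] else
          rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
        lengths <- pmax(200, round(rlnorm(n, p$contig_length_meanlog,
                                          p$contig_length_sdlog)))
        ct <- emit(n, lengths, members[[nm]]$target, gsub("[^A-Za-z0-9]", "", nm))
        contigs[[length(contigs) + 1]] <- ct
        # genes on these contigs
        for (k in seq_len(n)) {
          ng <- max(1L, as.integer(round(lengths[k] / 1000 * p$gene_density)))
          has_lin <- runif(ng) < p$taxon_assignment_rate
          gid <- sprintf("g%07d", gene_counter + seq_len(ng))
          gene_counter <- gene_counter + ng
          genes[[length(genes) + 1]] <- tibble::tibble(
            gene_id = gid, contig_id = ct$contig_id[k], sample_id = sid,
            percent_identity = round(runif(ng, 70, 100), 1),
            lineage = ifelse(has_lin, p$lineage, NA_character_))
          if (length(p$ko_repertoire) > 0) {
            has_ko <- runif(ng) < p$ko_rate
            if (any(has_ko)) {
              gene_ko[[length(gene_ko) + 1]] <- tibble::tibble(
                gene_id = gid[has_ko], contig_id = ct$contig_id[k],
                sample_id = sid,
                ko = sample(p$ko_repertoire, sum(has_ko), replace = TRUE))
            }
          }
        }
      }

      # unassigned background
      if (bg_target > 0 && scenario$background_contigs > 0) {
        n <- scenario$background_contigs
        lengths <- pmax(200, round(rlnorm(n, log(1200), 0.5)))
        ct <- emit(n, lengths, bg_target, "bg")
        contigs[[length(contigs) + 1]] <- ct
        ng_tot <- pmax(1L, as.integer(round(lengths / 1000)))
        gid <- sprintf("g%07d", gene_counter + seq_len(sum(ng_tot)))
        gene_counter <- gene_counter + sum(ng_tot)
        genes[[length(genes) + 1]] <- tibble::tibble(
          gene_id = gid,
          contig_id = rep(ct$contig_id, ng_tot), sample_id = sid,
          percent_identity = NA_real_, lineage = NA_character_)
      }

      # virus contigs in the 0.1 um fraction
      if (sm$filter_fraction_um == 0.1 && nrow(viruses$share) > 0) {
        vs <- dplyr::filter(viruses$share, .data$sample_id == sid)
        for (vi in seq_len(nrow(vs))) {
          mem <- dplyr::filter(viruses$members,
                               .data$cluster_id == vs$cluster_id[vi])
          lengths <- mem$length_bp
          cov_w <- lengths / sum(lengths)
          cov <- vs$target[vi] / 100 * scenario$total_coverage * cov_w
          depth <- cov / lengths
          if (scenario$noise_sd > 0) {
            depth <- depth * rlnorm(length(depth), 0, scenario$noise_sd)
          }
          contigs[[length(contigs) + 1]] <- tibble::tibble(
            contig_id = mem$contig_id, sample_id = sid,
            length_bp = as.integer(lengths), read_depth = depth)
        }
      }

      # ground truth: cellular members by pipeline OTU name; remainder
      # (background + virion fraction) is the unassigned pool
      tr <- tibble::tibble(
        sample_id = rep(sid, length(members)),
        otu_name = vapply(members, function(m) otu_display_name(m$profile$lineage),
                          character(1), USE.NAMES = FALSE),
        true_ra = vapply(members, `[[`, numeric(1), "target",
                         USE.NAMES = FALSE))
      truth[[length(truth) + 1]] <- dplyr::bind_rows(
        tr, tibble::tibble(sample_id = sid, otu_name = "unassigned",
                           true_ra = bg_target + v_share))
    }

    structure(list(
      samples = samples,
      contigs = dplyr::bind_rows(contigs),
      genes = dplyr::bind_rows(genes),
      gene_ko = if (length(gene_ko)) dplyr::bind_rows(gene_ko) else
        tibble::tibble(gene_id = character(), contig_id = character(),
                       sample_id = character(), ko = character()),
      truth = dplyr::bind_rows(truth),
      virus_truth = viruses$share,
      clusters = viruses$members[, c("cluster_id", "contig_id")],
      virus_hosts = viruses$hosts,
      virus_seqs = viruses$seqs,
      scenario = scenario
    ), class = "lake_sim")
  })
}

# Virus genomes, member contigs and per-0.1um-sample target shares with the
# requested host coupling. The coupled signal is built on the standardized
# host target trajectory plus independent Gaussian noise, then mapped
# affinely onto a positive share scale (Pearson correlation is affine
# invariant).
simulate_virus_layer <- function(scenario, samples) {
  empty <- list(
    share = tibble::tibble(sample_id = character(), cluster_id = character(),
                           target = numeric()),
    members = tibble::tibble(cluster_id = character(), contig_id = character(),
                             length_bp = integer(), sequence = character()),
    hosts = tibble::tibble(cluster_id = character(), host_otu = character(),
                           spacer_donor = logical(), kind = character()),
    seqs = character(0))
  if (length(scenario$virus_profiles) == 0) return(empty)

  virion <- dplyr::filter(samples, .data$filter_fraction_um == 0.1)
  if (nrow(virion) == 0) return(empty)
  otus <- setNames(scenario$otu_profiles,
                   vapply(scenario$otu_profiles, `[[`, character(1), "name"))

  members <- list(); shares <- list(); hosts <- list(); seqs <- character(0)
  for (v in scenario$virus_profiles) {
    genome <- random_dna(v$genome_length_bp)
    cut <- floor(seq(0, v$genome_length_bp, length.out = v$n_contigs + 1))
    mem <- tibble::tibble(
      cluster_id = v$name,
      contig_id = sprintf("%s_vc%02d", v$name, seq_len(v$n_contigs)),
      length_bp = as.integer(diff(cut)),
      sequence = substring(genome, cut[-length(cut)] + 1, cut[-1]))
    members[[v$name]] <- mem
    seqs[mem$contig_id] <- mem$sequence
    hosts[[v$name]] <- tibble::tibble(
      cluster_id = v$name, host_otu = v$host_otu,
      spacer_donor = v$spacer_donor,
      kind = if (v$n_contigs >= 2) "cluster" else "singleton")

    host <- otus[[v$host_otu]]
    h <- vapply(seq_len(nrow(virion)), function(i) {
      if (virion$depth_code[i] %in% host$depth_niche)
        host$season_response[[virion$season[i]]] else 0
    }, numeric(1))
    z <- if (sd(h) > 0) (h - mean(h)) / sd(h) else rep(0, length(h))
    eps <- rnorm(length(h))
    u <- v$coupling * z + sqrt(max(0, 1 - v$coupling^2)) * eps
    target <- pmax(0.02 * v$base_share, v$base_share * (1 + 0.35 * u))
    shares[[v$name]] <- tibble::tibble(
      sample_id = virion$sample_id, cluster_id = v$name, target = target)
  }
  list(share = dplyr::bind_rows(shares),
       members = dplyr::bind_rows(members),
       hosts = dplyr::bind_rows(hosts),
       seqs = seqs)
}

#' Plant CRISPR spacers from virus genomes
#'
#' Draws spacer-length substrings from the contigs of spacer-donor viruses
#' and mutates each base independently at `mutation_rate`, emulating the
#' divergence between an archived spacer and the circulating virus
#' population. The truth table records the source virus, host taxon and
#' realized identity, for recall scoring against [match_spacers()] output.
#'
#' @param sim A [simulate_lake()] result.
#' @param mutation_rate Per-base substitution probability.
#' @param spacer_length Spacer length in bp (default 32).
#' @param n_per_virus Spacers drawn per donor virus.
#' @param seed Seed for the spacer draw (defaults to the scenario seed + 1).
#' @return List with `spacers` (named character vector) and `truth` (tibble
#'   `spacer_id`, `cluster_id`, `host_taxon`, `source_contig`, `start`,
#'   `n_mutations`, `identity_pct`).
#' @export
plant_spacers <- function(sim, mutation_rate = 0, spacer_length = 32L,
                          n_per_virus = 8L, seed = NULL) {
  stopifnot(inherits(sim, "lake_sim"))
  donors <- dplyr::filter(sim$virus_hosts, .data$spacer_donor)
  if (nrow(donors) == 0) abort("no spacer-donor viruses in the scenario")
  otus <- setNames(
    lapply(sim$scenario$otu_profiles, function(p) otu_display_name(p$lineage)),
    vapply(sim$scenario$otu_profiles, `[[`, character(1), "name"))
  with_scenario_seed(seed %||% (sim$scenario$seed + 1L), {
    sp <- list(); truth <- list(); counter <- 0L
    for (ci in donors$cluster_id) {
      mem <- dplyr::filter(sim$clusters, .data$cluster_id == ci)
      seqs <- sim$virus_seqs[mem$contig_id]
      if (max(nchar(seqs)) < spacer_length) {
        abort("spacer length exceeds virus contig length")
      }
      host <- otus[[donors$host_otu[donors$cluster_id == ci]]]
      for (k in seq_len(n_per_virus)) {
        counter <- counter + 1L
        ok <- which(nchar(seqs) >= spacer_length)
        src <- ok[sample.int(length(ok), 1)]
        s0 <- sample(nchar(seqs[src]) - spacer_length + 1L, 1)
        raw <- substr(seqs[src], s0, s0 + spacer_length - 1L)
        bases <- strsplit(raw, "", fixed = TRUE)[[1]]
        mut <- runif(spacer_length) < mutation_rate
        if (any(mut)) {
          bases[mut] <- vapply(bases[mut], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        id <- sprintf("sp_%s_%03d", ci, k)
        sp[[id]] <- paste(bases, collapse = "")
        truth[[length(truth) + 1]] <- tibble::tibble(
          spacer_id = id, cluster_id = ci, host_taxon = host,
          source_contig = names(seqs)[src], start = s0 - 1L,
          n_mutations = sum(mut),
          identity_pct = (spacer_length - sum(mut)) / spacer_length * 100)
      }
    }
    list(spacers = unlist(sp), truth = dplyr::bind_rows(truth))
  })
}

#' The default lake scenario
#'
#' An idealized meromictic-lake community of about twenty members across the
#' seven depths, three filter fractions and eight sampling dates spanning
#' the three sampled seasons, with the field design's winter gap in the
#' lower zone. The interface is dominated in summer by a green-sulfur-
#' bacterium phototroph whose target trajectory collapses from 80% in
#' summer to 6% in winter and 1% in spring before rebounding; the lower
#' anoxic zone carries depth-restricted anaerobes, the upper oxic zone a
#' mixed photo/heterotroph assemblage. Two virus clusters positively
#' coupled to their hosts occupy the virion (0.1 um) fraction.
#'
#' @param seed Scenario seed.
#' @param noise_sd Multiplicative read-depth noise (0 for the noise-free
#'   variant).
#' @param taxon_assignment_rate Probability a gene carries its OTU lineage
#'   (1 for the noise-free variant).
#' @param n_dates Number of sampling dates (up to 8).
#' @return A `lake_scenario`.
#' @export
default_lake_scenario <- function(seed = 1L, noise_sd = 0.1,
                                  taxon_assignment_rate = 0.7,
                                  n_dates = 8L) {
  up <- c("U1", "U2", "U3"); lo <- c("L1", "L2", "L3")
  sr <- function(su, wi, sp) c(summer = su, winter = wi, spring = sp)
  op <- function(...) otu_profile(..., taxon_assignment_rate = taxon_assignment_rate)
  profs <- list(
    op("Chlorobium",
       "Bacteria;Chlorobi;Chlorobia;Chlorobiales;Chlorobiaceae;Chlorobium",
       "I", sr(80, 6, 1), contig_count_range = c(10L, 16L),
       ko_repertoire = c("K00855", "K01595", "K08928", "K11180", "K11181")),
    op("Synechococcus",
       "Bacteria;Cyanobacteria;Cyanophyceae;Synechococcales;Synechococcaceae;Synechococcus",
       up, sr(12, 1.5, 7), ko_repertoire = c("K02703", "K02706", "K01601")),
    op("Loktanella",
       "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Loktanella",
       up, sr(8, 10, 9), ko_repertoire = c("K00370", "K02274")),
    op("Actinobacterium",
       "Bacteria;Actinobacteria;Actinomycetia;Micrococcales;Microbacteriaceae;Candidatus Aquiluna",
       up, sr(7, 9, 8), ko_repertoire = c("K03320")),
    op("Flavobacterium",
       "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Flavobacterium",
       up, sr(8, 9, 9), ko_repertoire = c("K01183", "K05349")),
    op("Verrucomicrobia SW10",
       "Bacteria;Verrucomicrobia;Spartobacteria;Chthoniobacterales;Chthoniobacteraceae;SW10",
       up, sr(4, 5, 5)),
    op("Micromonas",
       "Eukaryota;Chlorophyta;Mamiellophyceae;Mamiellales;Mamiellaceae;Micromonas",
       up, sr(6, 0.5, 4), ko_repertoire = c("K01601", "K02703")),
    op("Pelagibacter",
       "Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacterales;Pelagibacteraceae;Pelagibacter",
       up, sr(5, 7, 6)),
    op("Desulfobacterium",
       "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfobacterales;Desulfobacteraceae;Desulfobacterium",
       c("I", lo), sr(8, 10, 10),
       ko_repertoire = c("K11180", "K11181", "K00394")),
    op("Cloacimonetes W5",
       "Bacteria;Cloacimonetes;Cloacimonadia;Cloacimonadales;Cloacimonadaceae;W5",
       c("L2", "L3"), sr(10, 12, 12), ko_repertoire = c("K00399")),
    op("Atribacteria JS1",
       "Bacteria;Atribacteria;JS1",
       "L3", sr(9, 11, 11)),
    op("Clostridium",
       "Bacteria;Firmicutes;Clostridia;Clostridiales;Clostridiaceae;Clostridium",
       lo, sr(5, 6, 6), ko_repertoire = c("K00925", "K00625")),
    op("Methanosarcina",
       "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosarcinaceae;Methanosarcina",
       c("L2", "L3"), sr(4, 5, 5), ko_repertoire = c("K00399", "K00402")),
    op("Anaerolinea",
       "Bacteria;Chloroflexi;Anaerolineae;Anaerolineales;Anaerolineaceae;Anaerolinea",
       lo, sr(3, 4, 4)),
    op("Gammaproteobacterium",
       "Bacteria;Proteobacteria;Gammaproteobacteria;Cellvibrionales;Halieaceae;Halioglobus",
       c(up, "I", lo), sr(6, 7, 7), ko_repertoire = c("K00370")),
    op("Planctomycetes",
       "Bacteria;Planctomycetes;Planctomycetia;Pirellulales;Pirellulaceae;Rhodopirellula",
       up, sr(3, 4, 4)),
    op("Parcubacteria",
       "Bacteria;Parcubacteria;Candidatus Adlerbacteria",
       c(up, "I", lo), sr(2, 3, 3)),
    op("Polaromonas",
       "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Comamonadaceae;Polaromonas",
       up, sr(4, 5, 5)),
    op("Acholeplasma",
       "Bacteria;Tenericutes;Mollicutes;Acholeplasmatales;Acholeplasmataceae;Acholeplasma",
       up, sr(0.5, 0.5, 0.5)),
    op("Halorubrum",
       "Archaea;Euryarchaeota;Halobacteria;Halobacteriales;Halorubraceae;Halorubrum",
       up, sr(0.4, 0.4, 0.4))
  )
  viruses <- list(
    virus_profile("CL-GSB-1", host_otu = "Chlorobium", coupling = 0.9,
                  genome_length_bp = 9000L, n_contigs = 3L, base_share = 10),
    virus_profile("CL-CYA-1", host_otu = "Synechococcus", coupling = 0.7,
                  genome_length_bp = 7000L, n_contigs = 2L, base_share = 6)
  )
  dates <- as.Date(c("2013-12-15", "2014-02-10", "2014-07-20", "2014-08-15",
                     "2014-10-10", "2014-11-20", "2014-12-12", "2015-01-15"))
  lake_scenario(profs, viruses, dates = dates[seq_len(n_dates)],
                noise_sd = noise_sd, seed = seed)
}
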