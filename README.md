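# meromix

Community analysis of metagenome time series from permanently stratified
(meromictic) lakes.

Meromictic lakes never mix: an oxic upper zone, a sharp oxic/anoxic
interface, and an anoxic lower zone each carry their own microbial
community, and at polar latitudes the extreme seasonal light cycle drives
those communities through large annual swings — most dramatically a
green-sulfur-bacterium (*Chlorobium*-type) phototroph layer at the
interface that dominates in summer and collapses through winter and
spring. `meromix` implements the contig-based analysis used to quantify
such systems from multi-depth, multi-season, size-fractionated (3.0, 0.8,
0.1 µm) shotgun metagenomes, and ships a synthetic stratified-lake
generator with known ground truth so the whole pipeline is testable
without any sequence download.

## What it computes

**Contig taxonomy and OTUs.** Each assembled contig is classified from the
taxonomic lineages of its predicted genes: at least 30 % of the genes must
carry a lineage, the taxon held by the most genes wins, and a contig whose
genes all disagree stays unassigned. The vote is hierarchical (species up
to domain; ties escalate one rank). Classified contigs are binned as OTUs
at the lowest assigned rank.

**Coverage-weighted abundance.** The relative abundance of an OTU in a
metagenome is

```
RA(OTU) = Σ_i (L_i · d_i) / Σ_j (L_j · d_j) × 100
```

with `L` contig length, `d` contig read depth, `i` over the OTU's contigs
and `j` over *all* contigs in the metagenome (including the unassigned
pool), so values are comparable across samples. OTUs reaching ≥ 1 % in at
least one metagenome are "abundant"; the rest are grouped as Other
Bacteria/Archaea/Eukarya/Viruses.

**Functional potential.** Per-metagenome KO abundances (summed read depth
of the distinct contigs carrying each KO) are aggregated into
pathway/enzyme abundances and normalized by each metagenome's total
KO-contig read depth, rescaled by the dataset mean of those totals.
Ambiguous roles (redox enzymes, homologous families) are resolved by
parameterized local alignment (match +2, mismatch −1, gap open −0.5, gap
extend −0.1) against labelled reference proteins.

**Viral linkage.** Viral cluster read depths are summed per time period
(calendar month), with clusters exceeding 4000 total read depth in any
period flagged abundant (strict inequality). CRISPR spacers are matched
against contigs at ≥ 97 % identity and ≥ 0.97 aligned fraction to link
viruses to hosts; clusters are expanded by ≥ 90 % identity / ≥ 98 %
alignment-fraction similarity; host–virus couplings are tested by Pearson
correlation.

**Community ecology.** Simpson's index of diversity; Bray–Curtis
similarity on square-root-transformed abundances; SIMPER decomposition of
within-season similarity and between-season dissimilarity into per-taxon
contributions; and a distance-based linear model (dbRDA via principal
coordinates with Lingoes correction) of the community against normalized
environmental drivers (depth, salinity, daylength, sunlight hours, air
temperature) with forward selection by adjusted R².

## Worked example

```r
library(meromix)
library(dplyr)

scenario <- default_lake_scenario(seed = 1, n_dates = 6)
sim <- simulate_lake(scenario)

bins <- bin_otus(assign_contig_taxonomy(sim$contigs, sim$genes))
ra   <- relative_abundance(sim$contigs, bins)

interface_peak <- function(season) {
  ids <- sim$samples$sample_id[sim$samples$depth_code == "I" &
           sim$samples$season == season & sim$samples$filter_fraction_um != 0.1]
  pk <- peak_relative_abundance(ra, samples = ids)
  pk$peak_ra[pk$otu_name == "Chlorobium"]
}
sprintf("summer %.1f%%, winter %.1f%%, spring %.1f%%",
        interface_peak("summer"), interface_peak("winter"),
        interface_peak("spring"))
#> "summer 74.4%, winter 5.5%, spring 1.0%"

abundant <- select_abundant(ra, sim$contigs, bins)
length(abundant)          #> 18
head(abundant, 3)         #> "Halioglobus" "Chlorobium" "Desulfobacterium"

grouped <- group_other(ra, abundant, distinct(bins, otu_name, domain))
cell <- sim$samples$sample_id[sim$samples$filter_fraction_um != 0.1]
fit <- dbrda_fit(bray_curtis(filter(grouped, sample_id %in% cell)),
                 env_normalize(sim$samples) |> filter(sample_id %in% cell),
                 selection = "forward")
glance(fit)
#> adj_r_squared axis1_pct_fitted axis1_pct_total pct_total_fitted n_variables
#>         0.526             94.5            52.2             55.2           4
```

The interface phototroph's recovered peak trajectory (74 % → 5.5 % → 1 %)
reproduces the planted summer-dominance / winter-collapse / spring-minimum
shape under the generator's default depth noise; the first dbRDA axis
carries ~95 % of the fitted community variation, driven by the seasonal
light variables and the depth/salinity gradient.

`run_pipeline(pipeline_config(out_dir))` runs every stage (simulate →
classify-contigs → abundance → kegg-profile → viral → ecology), writes all
tables as TSV plus a checksummed manifest, and is byte-identical on rerun
with the same seed.

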