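# sedarch

Downstream analytics for large metagenome-assembled-genome (MAG)
catalogs recovered from high-elevation sediment ecosystems.  Building
a sediment catalog (assembly, binning, annotation) is handled by
standard external tools; what comes after — the accounting and the
ecology/evolution statistics — is a pile of bespoke rules scattered
across methods sections.  `sedarch` implements that layer as tested,
composable R functions:

* **Catalog accounting** — MAG quality score
  (completeness − 5 × contamination), MIMAG tiering (high quality:
  completeness > 90 %, contamination < 5 %, 5S/16S/23S rRNA present,
  ≥ 18 tRNAs; medium: ≥ 50 % / < 10 %), the 60 % sub-contig rule for
  flagging eukaryotic contigs, species novelty against reference
  catalogs (known requires ANI ≥ 0.95 **and** aligned fraction ≥ 0.30),
  region/ecosystem/site exclusivity summaries, and gene rarefaction
  (5 % steps, 10 replicates).
* **Community ecology** — Shannon diversity, Bray–Curtis
  dissimilarity, PCoA, the distance–decay relationship (DDR) of
  community similarity with geographic (haversine, R = 6371 km) or
  vertical distance, and Sloan's neutral community model (NCM): the
  occurrence frequency of a taxon with mean relative abundance *p* is
  modeled as 1 − I_d(N m p, N m(1 − p)), fitting the migration rate
  *m* by nonlinear least squares; R² = 1 − SSE/SST may be negative for
  strongly non-neutral communities.
* **Chronology** — on time-calibrated trees (branch lengths in Ma):
  per-species *latest divergence* (age of the tip's parent node),
  classification into "possible ancient species" (PAS, latest
  divergence > 541 Ma, the Cryptozoic/Phanerozoic boundary) versus
  extant, habitat-group proportion curves over time, relative
  evolutionary distance (RED, 0 at the root to 1 at the leaves), and
  a stratified 200-MAG subsampler (phyla < 30 MAGs merged,
  largest-remainder allocation, 15 replicates).
* **BGC novelty** — dereplication of biosynthetic gene clusters
  (longest BGC per GCF per species), median-of-genes abundance,
  matched/novel calls at reference membership ≤ 900, group novelty
  (GCF novel if < 20 % of members mapped; GCC if < 40 %), and Ward
  clustering of samples on Bray–Curtis distances of GCC abundances.
* **KO enrichment** — per-Mb normalization of MAG × KO counts averaged
  per ecosystem, a prevalence filter (> 30 % of non-focal ecosystems),
  and the enrichment ratio r = (A_f − S_o)/(A_f + S_o) with
  enriched/reduced calls at |r| > 0.9.
* **Probe design** — 30-bp sliding windows at 15-bp steps, a
  conjunctive specificity filter (remove on off-target hits with
  E < 20 **and** coverage ≥ 60 % **and** identity ≥ 90 %), cross-genus
  uniqueness screening with a built-in ungapped match oracle, and
  selection of up to 10 probes at distinct loci.
* **Synthetic data** — seeded generators (`gen_time_tree`,
  `gen_mag_table`, `gen_ddr_community`, `gen_ncm_data`,
  `gen_ko_matrix`, `gen_bgc_catalog`, `gen_probe_genomes`) emitting
  every input format above with planted, recoverable ground truth and
  JSON truth sidecars, so each stage is testable without any
  sequencing data.

## Worked example

Generate a synthetic study and run three of the pipeline stages:

```r
library(sedarch)
cfg <- sim_config(seed = 42)

# Sloan neutral model: planted migration rate m = 0.1
ncm <- gen_ncm_data(cfg)
ncm_fit(ncm$data$p, ncm$data$freq, N = ncm$truth$N)
#> Neutral community model: m = 0.09904, N = 1000, R^2 = 0.969

# Distance decay: planted rate 0.002 / km
ddr <- gen_ddr_community(cfg)
pr  <- ddr_pairs(ddr$abundance, ddr$geo, "geographic")
ddr_fit(pr$similarity, pr$distance, log_distance = FALSE)
#> Distance-decay fit (geographic, ln(similarity) ~ distance)
#>   slope       -0.00199489
#>   intercept   -0.003855
#>   correlation -0.999
#>   pairs used  1225 (excluded 0)

# PAS classification on a 200-tip time tree, planted ancient fraction 0.4
tt  <- gen_time_tree(sim_config(seed = 42, ancient_fraction = 0.4))
cls <- classify_pas(latest_divergence(tt$tree))
table(cls)
#> cls
#>    PAS extant
#>     79    121
pas_group_summary(cls, setNames(tt$groups$group, tt$groups$species_id))$table
#>                eon
#> group           PAS extant
#>   Sediment only  28     54
#>   Shared         14     14
#>   Water only     37     53
```

The NCM fit recovers the planted migration rate to three decimals, the
DDR slope recovers the planted decay rate within 0.3 %, and 79/200 =
0.395 of tips classify as PAS against the planted 0.4 (the residual is
the tie-handling at the eon boundary, bounded by one cherry).

## Layout

```
R/                     implementation (one file per pipeline stage)
tests/testthat/        unit + property + end-to-end acceptance tests
scripts/acceptance.R   headline-statistics reproduction script
vignettes/sedarch-methods.Rmd   model and design notes
```
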