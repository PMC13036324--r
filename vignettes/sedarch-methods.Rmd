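---
title: "sedarch: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sedarch: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedarch)
```

`sedarch` is the downstream analytical layer for sediment MAG
catalogs: the accounting rules, ecology statistics, and
divergence-time classification that sit between an assembled catalog
and its biological conclusions.  This vignette documents the models,
the tunable parameters, the numerical choices, and the places where
the design was genuinely open and a decision had to be made.

## Catalog accounting

**Quality score.** `quality_score()` is the linear composite
completeness − 5 × contamination, on the percent scale.  It is
deliberately unbounded below: a bin with 60 % completeness and 15 %
contamination scores −15, and catalog filters conventionally keep
score > 50.

**MIMAG tiers.** `mimag_tier()` applies the standard two-tier rule:
high quality needs completeness > 90 (strict), contamination < 5, all
three rRNA genes, and ≥ 18 tRNAs; medium needs completeness ≥ 50 and
contamination < 10.  The tiers partition every record, and every
high-tier record satisfies the medium numeric criteria by
construction — both properties are asserted in the test suite.

**Eukaryotic-contig rule.** Contigs are windowed at 1 kb / 0.5 kb
steps (0-based half-open coordinates; trailing partial windows are
discarded, so a contig shorter than 1 kb has zero windows).  A contig
is flagged when **at least** 60 % of windows have a eukaryote best
hit.  The inclusive reading of "60 % of the sub-contigs" was chosen
over a strict one; the threshold is an argument for users who prefer
the other convention.  Zero-window contigs are not flagged, with a
warning rather than an error, since upstream filters already remove
sub-window contigs.

**Species novelty.** The species boundary in this domain is
ANI ≥ 0.95 with aligned fraction ≥ 0.30.  We classify a species as
*known* in a reference catalog only when some match satisfies both,
and as novel otherwise — i.e. novelty is the logical complement of
the clustering criterion, not the literal conjunction "ANI < 0.95 and
AF < 0.30" (which would call a 0.99-ANI/0.2-AF match "novel by
neither-criterion" yet "known" under the clustering rule; the two
readings genuinely conflict and the complement is the one consistent
with dereplication).  Per-catalog flags and the all-catalog
`unique_to_catalog` flag are both emitted so either count can be
reported.

**Percent rounding.** Printed report fields round half-up
(`round_half_up()`), because banker's rounding in base `round()`
changes second-decimal percentages; raw floats are retained
everywhere internally.

## Community ecology

**Distance decay.** `ddr_fit()` defaults to the power-law form
(log similarity on log distance), the standard distance–decay model;
`log_distance = FALSE` gives the exponential form whose slope is
minus the decay rate per km, which is the form the synthetic
generator plants.  Pairs with zero distance (replicate coordinates)
or zero similarity (disjoint communities) have no defined log and are
excluded and counted.  At least 3 usable pairs are required.
Geographic distance is the haversine on a 6371-km sphere; vertical
distance is the absolute elevation difference in metres.  Fits are
intended per region; pooling across regions is the caller's choice by
subsetting samples.

**Neutral community model.** `ncm_fit()` fits Sloan's model: the
predicted occurrence frequency of a taxon with mean relative
abundance $p$ is $1 - I_d(Nmp,\; Nm(1-p))$, the regularized
incomplete beta function at detection limit $d$.  Only the migration
rate $m \in (0,1]$ is fitted (Levenberg–Marquardt, start 0.5,
bounded); $N$ is supplied by the caller (typically the mean per-sample
count depth) and $d$ defaults to $1/N$, the one-read detection
equivalent used by common implementations — the exact $N$ and $d$
conventions differ between studies and are therefore explicit
arguments.  $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ is unbounded below;
communities assembled deterministically produce negative values, and
the package represents and tests that regime rather than clamping it.
Non-convergence returns a structured failure object rather than an
error, so screening loops can continue.

**Ordination and tests.** PCoA is classical metric scaling
(`stats::cmdscale`); negative eigenvalues of non-Euclidean
dissimilarities are reported but their axes dropped.  Group
comparisons use Kruskal–Wallis plus two-sided pairwise Mann–Whitney
tests with Benjamini–Hochberg adjustment, significant at adjusted
p < 0.05.  `wilcox.test()`'s exact/normal-approximation switching
(exact for small samples without ties, tie-corrected normal
approximation otherwise) is used as-is.

## Chronology

**Latest divergence.** A species' "latest divergence" is
operationalized as the age of its tip's immediate parent node on the
time-calibrated tree — the most recent split involving that lineage.
Node ages are path lengths to the (extant, age-0) tips; trees must be
ultrametric within a relative tolerance of 1e-6, and violations error
with the offending tip names, since a non-ultrametric "time tree" is
an upstream calibration bug rather than something to average over.

**PAS boundary.** The Cryptozoic/Phanerozoic boundary defaults to
541 Ma, with ties going to extant (PAS requires age strictly
\> boundary, matching "prior to 541 Ma").  Some displays draw the
line at 600 Ma; `boundary_ma` is exposed for that convention rather
than hard-coding either.

**RED.** Relative evolutionary distance interpolates node depth from
0 (root) to 1 (leaves): for node $n$ with parent $p$, branch $d$, and
$u = d$ + mean distance from $n$ to its descendant leaves,
$\mathrm{RED}(n) = \mathrm{RED}(p) + (d/u)(1-\mathrm{RED}(p))$.  The
implementation is a two-pass linear-time traversal; the test suite
checks it against an independent brute-force recursion (full node
distance matrix + descendant sets) on 1,000 random trees at 1e-12.
RED is computed on whatever tree it is given — time-calibrated by
default in this pipeline, but a substitution-length tree is equally
valid input since the convention differs between studies.

**Stratified subsampler.** For divergence-time estimation on large
catalogs, 200 MAGs are drawn with phyla under 30 members merged into
one stratum and per-stratum allocation proportional to stratum size
under largest-remainder rounding, repeated 15 times.  A description
of per-phylum normal approximations sometimes attached to this
procedure is not implementable as a sampling scheme as written;
proportional allocation is the deterministic, testable choice (the
largest-remainder guarantee — every stratum within one individual of
its exact quota — is asserted in the tests).

## BGC novelty

Dereplication keeps the longest BGC per (GCF, species), ties broken
by lexicographically smallest id so reruns are stable.  BGC abundance
is the median of its biosynthetic genes per sample (even counts: mean
of the two middle values); GCF/GCC abundance is the sum over
representative BGCs.  A BGC is *matched* when its best reference-GCF
membership value is ≤ 900 (smaller is better in that scale), novel
otherwise, including no-hit.  Group novelty follows the
mapped-fraction reading: a GCF is novel when strictly < 20 % of its
members are mapped, a GCC when < 40 % — the inverted phrasing
("proportion of novel BGCs < 0.2") that appears in some descriptions
contradicts this, and the mapped-fraction version is the one
consistent with novelty increasing as fewer members map; both the
mapped and novel fractions are returned so either statistic can be
quoted.  Ward clustering of samples runs `hclust` method `ward.D` —
the Lance–Williams recurrence applied directly to the Bray–Curtis
dissimilarities — rather than `ward.D2`, which squares them; with a
non-Euclidean input neither is "correct" and the direct form matches
the common description "Ward clustering based on Bray–Curtis".

## KO enrichment

Counts are normalized per MAG by genome size (Mb) and averaged over
the MAGs of each ecosystem.  KOs present in strictly more than 30 %
of the non-focal ecosystems are *prevalent*; only prevalent KOs enter
the ratio.  The enrichment ratio is
$r = (A_f - S_o)/(A_f + S_o)$ with $S_o$ the **sum** over non-focal
ecosystems, enriched at $r > 0.9$ and reduced at $r < -0.9$ (both
strict; $A_f > 19\,S_o$ for enrichment).  Whether the comparison
should pool the other ecosystems or be taken against each one
separately is ambiguous in prose descriptions; the sum is the default
and `method = "per_ecosystem"` provides the stricter all-ecosystems
variant.  Presence means normalized abundance exactly > 0 — no
pseudo-counts, so the statistic is invariant under global count
scaling (a tested property).  Two focal classes (Qilian Saline Lake
sediment, Tibet Freshwater Lake sediment) are both excluded from the
prevalence denominator and analyzed independently.

## Probe design

Candidates are fixed 30-mers on a 15-bp grid; the final 20–30 nt
trimming applied in wet-lab probe sets is not algorithmically
specified anywhere, so the pipeline reports full 30-mers.  The
specificity criteria (E < 20, coverage ≥ 60 %, identity ≥ 90 %) are
read **conjunctively** — a hit must satisfy all three to disqualify a
candidate — because E < 20 alone matches nearly everything and a
disjunctive reading would empty every candidate set.  The unusually
permissive E-value cutoff is kept as the literal default and exposed
as an argument.  The in-package match oracle scans both strands for
ungapped matches with bounded mismatches (identity
$100(30-\mathrm{mm})/30$, coverage 100, evalue = mismatch count as a
documented monotone surrogate); it replaces an external aligner at
desk scale and is itself validated against exhaustive string
comparison in the tests.  Identical window sequences receive
identical hits and therefore share a fate.  Probe-set selection takes
up to 10 mutually non-overlapping windows (distinct loci), ranked by
fewest near-miss hits then coordinate; a shortfall is a warning.

## Synthetic data: what it emulates, and what it does not

All generators hang off a single `sim_config()` seed, with one derived
RNG stream per artifact, so identical configurations give
byte-identical files (`sim_write()` emits Newick/FASTA/TSV plus a
JSON truth sidecar consumed only by tests).

* `gen_time_tree()` draws a coalescent tree and rescales it so the
  planted fraction of tips has parent age > 541 Ma; the planted PAS
  labels are bookkept from the scaled tree itself, so recovery checks
  are exact under floating point.  Tie cherries at the boundary can
  shift the realized fraction by one cherry, which is why recovery is
  asserted within ±0.05 at 200 tips.
* `gen_ddr_community()` places samples on a south–north meridian
  transect (lat 29–38°, lon 90°, elevations 3000–4200 m rising along
  it) and builds each community as an exp(−λd) mixture of its
  neighbor plus a fresh, disjoint species block.  Along a meridian
  great-circle distances are exactly additive, so the noise-free
  Bray–Curtis similarity of *every* pair is exactly exp(−λd) — the
  planted decay (default λ = 0.002/km, i.e. similarity 0.37 at
  500 km) is recoverable by construction.  Lognormal abundance noise
  (sd 0.05 on the log scale) is applied afterwards.  λ = 0 is
  accepted as the degenerate flat case; negative rates are rejected.
* `gen_ncm_data()` simulates detection frequencies from the model
  curve at the planted (N = 1000, m = 0.1), either exactly or through
  binomial detection over 50 samples — the two noise regimes the fit
  tolerances are derived from.
* `gen_ko_matrix()` plants enriched KOs with trace presence in five
  non-focal ecosystems (passing prevalence while keeping
  $S_o \ll A_f/19$) and broad background KOs at comparable abundance
  everywhere (ratios near −0.87, safely inside ±0.9).  Background KOs
  are not individually controlled against the *reduced* call, so
  planted-truth checks are exact for the enriched set and one-sided
  for the reduced set.
* `gen_bgc_catalog()` draws mapped-member counts inside each GCF's
  novelty band (strictly < 20 % or ≥ 40 %), so group classification
  is exact; gene abundances across 12 samples form three planted
  blobs with distinct GCC profiles for the Ward stage.
* `gen_probe_genomes()` copies selected target windows verbatim into
  off-target genomes; "unique" windows are simply never copied, which
  is sufficient because a ≥ 27/30-base chance match in a few kb of
  random sequence has negligible probability.

What passing these tests shows is that each statistic recovers
structure *it was built to detect* under its own generative
assumptions.  Real catalogs violate those assumptions in known ways —
spatially autocorrelated environments rather than a clean transect,
compositional and depth artifacts in abundance, non-ultrametric noise
in time calibration, homologous (not exact-copy) off-target
sequence — so test recovery bounds are not error bars for field data.

## Problem sizes and runtime

The default study conditions are 200 tree tips, 50 samples × 500
species for ecology, 16 ecosystems × 5 MAGs × 200 KOs, 300 BGCs, and
two 1.8-kb target contigs against three 2-kb off-targets; the full
suite (≈ 1,700 assertions, including the 1,000-tree RED oracle sweep)
runs in about half a minute on one CPU.

## Known limitations

* No environmental-covariate modeling (pH, salinity, temperature);
  distance is the only predictor in the DDR stage.
* The NCM fit estimates m only; N is an input, as in most
  implementations, and results are conditional on it.
* The probe stage models external screening databases as user-supplied
  labeled FASTA sets and performs no thermodynamic (Tm, secondary
  structure) screening.
* TPM quantification, ANI/AF computation, tree inference and
  calibration, and BGC detection are out of scope: the package
  consumes their tabular/Newick/FASTA outputs.
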