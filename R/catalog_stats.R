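# MAG catalog accounting: quality scoring, MIMAG tiering, eukaryotic
# contig flagging, species novelty, exclusivity, gene rarefaction.

#' MAG quality score
#'
#' Score = completeness - 5 * contamination, both on the percent scale.
#' Catalog convention keeps MAGs with score > 50.  The score may be
#' negative for heavily contaminated bins.
#'
#' @param completeness completeness percent in \[0, 100\].
#' @param contamination contamination percent, >= 0.
#' @return numeric score vector (percent scale).
#' @export
#' @examples
#' quality_score(75.9, 3.5)  # 58.4
quality_score <- function(completeness, contamination) {
  if (any(is.na(completeness)) || any(is.na(contamination)))
    stopf("quality_score: missing completeness or contamination")
  if (any(completeness < 0 | completeness > 100))
    stopf("completeness must be in [0, 100]")
  if (any(contamination < 0))
    stopf("contamination must be >= 0")
  completeness - 5 * contamination
}

#' MIMAG quality tier of a MAG record
#'
#' High quality requires completeness > 90, contamination < 5, all
#' three rRNA genes (5S, 16S, 23S) and at least 18 tRNAs.  Medium
#' quality requires completeness >= 50 and contamination < 10.
#' Everything else fails.  High-tier records always satisfy the
#' medium-tier numeric criteria.
#'
#' @param mags data frame with columns `completeness`, `contamination`,
#'   `has_rrna_5s`, `has_rrna_16s`, `has_rrna_23s`, `n_trna`.
#' @return factor vector with levels `high`, `medium`, `fail`.
#' @export
mimag_tier <- function(mags) {
  assert_cols(mags, c("completeness", "contamination", "has_rrna_5s",
                      "has_rrna_16s", "has_rrna_23s", "n_trna"), "MAG table")
  high <- mags$completeness > 90 & mags$contamination < 5 &
    mags$has_rrna_5s & mags$has_rrna_16s & mags$has_rrna_23s &
    mags$n_trna >= 18
  medium <- mags$completeness >= 50 & mags$contamination < 10
  tier <- ifelse(high, "high", ifelse(medium, "medium", "fail"))
  factor(tier, levels = c("high", "medium", "fail"))
}

#' Flag a contig as eukaryotic from sub-contig window hits
#'
#' A contig is split upstream into 1-kb windows at 0.5-kb steps and
#' each window carries a best-hit domain label.  The contig is flagged
#' when at least 60\% of its windows have a eukaryote best hit
#' (inclusive threshold).
#'
#' @param window_hits character vector of per-window best-hit labels,
#'   among `eukaryote`, `prokaryote`, `virus`, `none`.
#' @param threshold flagging fraction, default 0.60.
#' @return logical scalar.
#' @export
flag_eukaryotic <- function(window_hits, threshold = 0.60) {
  if (length(window_hits) == 0) {
    warnf("contig has zero windows; not flagged")
    return(FALSE)
  }
  bad <- setdiff(unique(window_hits),
                 c("eukaryote", "prokaryote", "virus", "none"))
  if (length(bad) > 0)
    stopf("unknown window hit label(s): %s", paste(bad, collapse = ", "))
  mean(window_hits == "eukaryote") >= threshold
}

#' Sub-contig window count for a contig length
#'
#' 1,000-bp windows at 500-bp steps, 0-based half-open coordinates;
#' trailing partial windows are discarded.
#'
#' @param contig_length contig length in bp.
#' @param window window size bp (default 1000).
#' @param step step size bp (default 500).
#' @return integer number of windows (0 for contigs shorter than one
#'   window).
#' @export
contig_window_count <- function(contig_length, window = 1000, step = 500) {
  ifelse(contig_length < window, 0L,
         as.integer(floor((contig_length - window) / step) + 1))
}

REFERENCE_CATALOGS <- c("GTDB", "GEM", "SMAG", "TPMC-A")

#' Classify species novelty against reference catalogs
#'
#' A species is *known* in a catalog when some reference genome matches
#' it at ANI >= 0.95 and aligned fraction (AF) >= 0.30; otherwise it is
#' novel against that catalog.  A species with no recorded match is
#' novel.  A species novel against every catalog is *unique* to this
#' catalog.
#'
#' @param species_ids character vector of all species ids to classify.
#' @param matches data frame with columns `species_id`, `catalog`,
#'   `ani`, `af` (fractions in \[0, 1\]); one row per best match, rows
#'   may be absent for species/catalog pairs with no match.
#' @param catalogs catalog names considered (default the four standard
#'   references).
#' @param ani_min,af_min the known-species thresholds.
#' @return data frame with one row per species: logical
#'   `novel_<catalog>` columns and `unique_to_catalog`.
#' @export
classify_novel <- function(species_ids, matches,
                           catalogs = REFERENCE_CATALOGS,
                           ani_min = 0.95, af_min = 0.30) {
  if (nrow(matches) > 0) {
    assert_cols(matches, c("species_id", "catalog", "ani", "af"),
                "match table")
    bad <- setdiff(unique(matches$catalog), catalogs)
    if (length(bad) > 0)
      stopf("unknown reference catalog(s): %s", paste(bad, collapse = ", "))
    if (any(matches$ani < 0 | matches$ani > 1 | matches$af < 0 | matches$af > 1))
      stopf("ANI and AF must be fractions in [0, 1]")
  }
  out <- data.frame(species_id = species_ids, stringsAsFactors = FALSE)
  for (cat in catalogs) {
    m <- matches[matches$catalog == cat &
                   matches$ani >= ani_min & matches$af >= af_min, , drop = FALSE]
    known <- species_ids %in% m$species_id
    out[[paste0("novel_", gsub("-", "_", cat))]] <- !known
  }
  flagcols <- grep("^novel_", names(out), value = TRUE)
  out$unique_to_catalog <- Reduce(`&`, out[flagcols])
  out
}

#' Exclusivity summary of species clusters
#'
#' A species is region- (ecosystem-, site-) exclusive when the set of
#' region (ecosystem, site) labels across its member MAGs has size 1.
#' Percentages are reported against all species and, separately,
#' against non-singleton species (>= 2 member MAGs), rounded half-up
#' to 2 decimal places.
#'
#' @param mags data frame with columns `mag_id`, `species_id`,
#'   `region`, `ecosystem`, `site_id`.
#' @return list with `counts` (data frame per label kind) and scalars
#'   `n_species`, `n_nonsingleton`.
#' @export
exclusivity_summary <- function(mags) {
  if (nrow(mags) == 0) stopf("empty MAG catalog")
  assert_cols(mags, c("mag_id", "species_id", "region", "ecosystem",
                      "site_id"), "MAG table")
  sp <- split(mags, mags$species_id)
  n_species <- length(sp)
  n_mags <- vapply(sp, nrow, integer(1))
  nonsingleton <- n_mags >= 2
  kinds <- c(region = "region", ecosystem = "ecosystem", site = "site_id")
  rows <- lapply(names(kinds), function(kind) {
    col <- kinds[[kind]]
    excl <- vapply(sp, function(d) length(unique(d[[col]])) == 1, logical(1))
    data.frame(
      label = kind,
      n_exclusive = sum(excl),
      pct_exclusive = percent(sum(excl), n_species),
      n_exclusive_nonsingleton = sum(excl & nonsingleton),
      pct_exclusive_nonsingleton = if (any(nonsingleton))
        percent(sum(excl & nonsingleton), sum(nonsingleton)) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  list(counts = do.call(rbind, rows),
       n_species = n_species,
       n_nonsingleton = sum(nonsingleton))
}

#' Gene-catalog rarefaction curve
#'
#' Subsamples the gene set at fractions `step, 2*step, ..., 1` without
#' replacement and reports the mean number of distinct gene clusters
#' over `reps` replicates per fraction.
#'
#' @param gene_cluster named character vector mapping gene id to
#'   cluster id (names = gene ids; unnamed is accepted).
#' @param step sampling fraction step (default 0.05).
#' @param reps replicates per fraction (default 10).
#' @param seed RNG seed.
#' @return data frame with columns `fraction`, `n_genes`,
#'   `mean_clusters`.
#' @export
rarefaction_curve <- function(gene_cluster, step = 0.05, reps = 10,
                              seed = 1) {
  if (length(gene_cluster) == 0) stopf("empty gene-to-cluster map")
  g <- length(gene_cluster)
  fractions <- seq(step, 1, by = step)
  # guard the endpoint against floating-point drift in seq()
  if (abs(fractions[length(fractions)] - 1) < 1e-9) {
    fractions[length(fractions)] <- 1
  } else if (fractions[length(fractions)] < 1) {
    fractions <- c(fractions, 1)
  }
  with_stream(seed, "rarefaction", {
    rows <- lapply(fractions, function(f) {
      n <- floor(f * g + 1e-9)
      if (n == 0) return(data.frame(fraction = f, n_genes = 0L,
                                    mean_clusters = 0))
      counts <- vapply(seq_len(reps), function(r) {
        length(unique(gene_cluster[sample.int(g, n)]))
      }, numeric(1))
      data.frame(fraction = f, n_genes = n, mean_clusters = mean(counts))
    })
    do.call(rbind, rows)
  })
}

#' Contig-removal bookkeeping
#'
#' @param initial initial contig count.
#' @param removed removed contig count, <= initial.
#' @return list with `removed`, `initial`, `pct` (2 dp, half-up).
#' @export
#' @examples
#' removal_bookkeeping(7183800, 73230)$pct  # 1.02
removal_bookkeeping <- function(initial, removed) {
  if (removed > initial) stopf("removed (%s) exceeds initial (%s)",
                               removed, initial)
  if (initial <= 0) stopf("initial contig count must be positive")
  list(removed = removed, initial = initial,
       pct = percent(removed, initial))
}
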