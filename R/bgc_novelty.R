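# BGC catalog accounting: dereplication, abundance aggregation,
# novelty classification, and Ward clustering of samples.

BGC_CATEGORIES <- c("PKSI", "PKSother", "NRPS", "RiPPs", "Saccharides",
                    "Terpene", "PKS-NRP_Hybrids", "Others")

#' Dereplicate BGCs within (GCF, species) pairs
#'
#' Keeps the single longest BGC per gene-cluster-family/species pair;
#' ties are broken by the lexicographically smallest `bgc_id`.
#'
#' @param records data frame with columns `bgc_id`, `species_id`,
#'   `length` (bp).
#' @param assignments data frame with columns `bgc_id`, `gcf_id`
#'   (and optionally `gcc_id`); every record must be assigned.
#' @return the representative subset of `records` with `gcf_id`
#'   (and `gcc_id` if present) joined on.
#' @export
dereplicate_bgcs <- function(records, assignments) {
  assert_cols(records, c("bgc_id", "species_id", "length"), "BGC table")
  assert_cols(assignments, c("bgc_id", "gcf_id"), "assignment table")
  miss <- setdiff(records$bgc_id, assignments$bgc_id)
  if (length(miss) > 0)
    stopf("BGC(s) without GCF assignment: %s",
          paste(head(miss, 5), collapse = ", "))
  idx <- match(records$bgc_id, assignments$bgc_id)
  records$gcf_id <- assignments$gcf_id[idx]
  if ("gcc_id" %in% names(assignments))
    records$gcc_id <- assignments$gcc_id[idx]
  # longest first, then lexicographic id: first row per pair wins
  ord <- order(records$gcf_id, records$species_id, -records$length,
               records$bgc_id)
  r <- records[ord, , drop = FALSE]
  keep <- !duplicated(paste(r$gcf_id, r$species_id, sep = "\r"))
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample metagenomic abundance of one BGC
#'
#' The abundance of a BGC in a sample is the median abundance of its
#' biosynthetic genes (even gene counts take the mean of the two
#' middle values).
#'
#' @param gene_abund genes x samples numeric matrix (>= 1 gene).
#' @return named numeric vector of per-sample abundances.
#' @export
bgc_abundance <- function(gene_abund) {
  gene_abund <- as.matrix(gene_abund)
  if (nrow(gene_abund) == 0) stopf("BGC has zero biosynthetic genes")
  apply(gene_abund, 2, median)
}

#' Summed GCF/GCC abundance profiles over representative BGCs
#'
#' @param bgc_abund representative-BGCs x samples abundance matrix
#'   with row names = bgc ids.
#' @param group named character vector mapping bgc id to group id
#'   (GCF or GCC).
#' @return groups x samples matrix of summed abundances.
#' @export
gcf_gcc_abundance <- function(bgc_abund, group) {
  bgc_abund <- as.matrix(bgc_abund)
  g <- group[rownames(bgc_abund)]
  if (any(is.na(g))) stopf("representative BGC(s) without group id")
  rowsum(bgc_abund, g)
}

#' Classify a BGC as matched or novel against reference GCF models
#'
#' A BGC is matched when its best reference-GCF membership value is
#' <= `threshold` (900, the reference-database convention); BGCs with
#' no hit or only larger membership values are novel.
#'
#' @param membership numeric vector of best membership values; NA = no
#'   hit recorded.
#' @param threshold matched-BGC membership cutoff (default 900).
#' @return logical vector, TRUE = novel.
#' @export
classify_bgc_novel <- function(membership, threshold = 900) {
  if (any(membership < 0, na.rm = TRUE)) stopf("negative membership value")
  is.na(membership) | membership > threshold
}

#' Group-level (GCF/GCC) novelty from member BGC flags
#'
#' A GCF is novel when strictly less than 20\% of its member BGCs are
#' mapped to the reference; a GCC when strictly less than 40\% are.
#'
#' @param mapped logical vector over the group's member BGCs
#'   (TRUE = mapped to a reference GCF).
#' @param level `"GCF"` or `"GCC"`.
#' @return list with `novel` (logical), `mapped_fraction`, and
#'   `novel_fraction` (= 1 - mapped fraction, the complementary
#'   statistic).
#' @export
classify_group_novel <- function(mapped, level = c("GCF", "GCC")) {
  level <- match.arg(level)
  if (length(mapped) == 0) stopf("empty group")
  cutoff <- if (level == "GCF") 0.20 else 0.40
  frac <- mean(mapped)
  list(novel = frac < cutoff, mapped_fraction = frac,
       novel_fraction = 1 - frac, level = level, cutoff = cutoff)
}

#' Category counts and percentages of a BGC table
#'
#' @param categories character vector of BGC categories (must be among
#'   the 8 standard groups).
#' @return data frame with `category`, `n`, `pct` (2 dp, half-up);
#'   empty input yields an empty summary with a warning.
#' @export
category_summary <- function(categories) {
  if (length(categories) == 0) {
    warnf("empty BGC table; empty summary")
    return(data.frame(category = character(0), n = integer(0),
                      pct = numeric(0)))
  }
  bad <- setdiff(unique(categories), BGC_CATEGORIES)
  if (length(bad) > 0)
    stopf("unknown BGC category: %s", paste(bad, collapse = ", "))
  tab <- table(factor(categories, levels = BGC_CATEGORIES))
  data.frame(category = names(tab), n = as.integer(tab),
             pct = percent(as.integer(tab), length(categories)),
             stringsAsFactors = FALSE)
}

#' Ward clustering of samples by GCC abundance
#'
#' Agglomerative Ward linkage (Lance-Williams recurrence applied
#' directly to the Bray-Curtis dissimilarities, `hclust` method
#' `ward.D`) cut into `k` clusters.
#'
#' @param abund samples x GCC abundance matrix with sample row names.
#' @param k number of clusters (default 3).
#' @param ecosystems optional named character vector of sample
#'   ecosystem labels for the composition table.
#' @return list with `clusters` (named integer vector), `tree`
#'   (`hclust`), `newick` (dendrogram as a Newick string), and
#'   `composition` (cluster x ecosystem table or NULL).
#' @export
ward_cluster_samples <- function(abund, k = 3, ecosystems = NULL) {
  abund <- as.matrix(abund)
  if (k > nrow(abund))
    stopf("k (%d) exceeds sample count (%d)", k, nrow(abund))
  d <- vegan::vegdist(abund, method = "bray")
  hc <- hclust(d, method = "ward.D")
  cl <- cutree(hc, k = k)
  comp <- NULL
  if (!is.null(ecosystems)) {
    comp <- table(cluster = cl, ecosystem = ecosystems[names(cl)])
  }
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(clusters = cl, tree = hc, newick = nwk, composition = comp)
}
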