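# Differential-KO statistic: per-Mb normalization, prevalence filter,
# the +/-0.9 enrichment ratio, singleton/conserved classification.

#' Per-ecosystem normalized KO profiles
#'
#' Each MAG's KO count is divided by its genome size (Mb) and the
#' per-Mb abundances are averaged over the MAGs of each ecosystem:
#' A(e, k) = mean over MAGs m in e of count(m, k) / size(m).
#'
#' @param counts MAGs x KOs nonnegative count matrix with row names.
#' @param sizes named numeric vector of genome sizes in Mb (> 0),
#'   covering all MAGs.
#' @param ecosystems named character vector of ecosystem labels
#'   covering all MAGs.
#' @return ecosystems x KOs matrix of mean per-Mb abundances.
#' @export
normalize_profiles <- function(counts, sizes, ecosystems) {
  counts <- as.matrix(counts)
  mags <- rownames(counts)
  if (is.null(mags)) stopf("count matrix needs MAG row names")
  if (any(!mags %in% names(sizes)))
    stopf("MAG(s) missing genome size: %s",
          paste(head(setdiff(mags, names(sizes)), 5), collapse = ", "))
  if (any(!mags %in% names(ecosystems)))
    stopf("MAG(s) missing ecosystem label")
  sz <- sizes[mags]
  if (any(sz <= 0)) stopf("genome sizes must be positive")
  if (any(counts < 0)) stopf("negative KO counts")
  per_mb <- counts / sz
  eco <- ecosystems[mags]
  sums <- rowsum(per_mb, eco)
  sums / as.numeric(table(eco)[rownames(sums)])
}

#' Prevalence filter over non-focal ecosystems
#'
#' A KO is prevalent when it is present (abundance > 0) in strictly
#' more than `threshold` of the non-focal ecosystems.
#'
#' @param profiles ecosystems x KOs matrix from [normalize_profiles()].
#' @param focal character vector of focal ecosystem(s) excluded from
#'   the prevalence denominator.
#' @param threshold prevalence fraction (default 0.30, strict).
#' @return character vector of prevalent KO ids.
#' @export
prevalence_filter <- function(profiles, focal, threshold = 0.30) {
  others <- setdiff(rownames(profiles), focal)
  if (length(others) < 2) stopf("need at least 2 non-focal ecosystems")
  present <- colSums(profiles[others, , drop = FALSE] > 0)
  colnames(profiles)[present / length(others) > threshold]
}

#' Enrichment ratio of KOs in a focal ecosystem
#'
#' r = (A_f - S_o) / (A_f + S_o), where A_f is the focal ecosystem's
#' per-Mb abundance and S_o the sum over the non-focal ecosystems
#' (`method = "sum"`, the default).  A KO is `enriched` when r > 0.9
#' and `reduced` when r < -0.9 (both strict).  With
#' `method = "per_ecosystem"` the ratio is computed against each
#' non-focal ecosystem separately and a KO is enriched/reduced only
#' when every per-ecosystem ratio crosses the cutoff; the reported r
#' is then the least extreme one.
#'
#' @inheritParams prevalence_filter
#' @param focal single focal ecosystem name.
#' @param cutoff ratio cutoff (default 0.9).
#' @param method `"sum"` or `"per_ecosystem"`.
#' @return data frame with `ko_id`, `ratio`, `label` (`enriched`,
#'   `reduced`, `neither`); KOs with A_f + S_o = 0 are skipped with a
#'   warning.
#' @export
enrichment_ratio <- function(profiles, focal, cutoff = 0.9,
                             method = c("sum", "per_ecosystem")) {
  method <- match.arg(method)
  if (length(focal) != 1 || !focal %in% rownames(profiles))
    stopf("focal must name one ecosystem present in the profiles")
  others <- setdiff(rownames(profiles), focal)
  a_f <- profiles[focal, ]
  if (method == "sum") {
    s_o <- colSums(profiles[others, , drop = FALSE])
    denom <- a_f + s_o
    skip <- denom == 0
    if (any(skip))
      warnf("%d KO(s) absent everywhere; skipped", sum(skip))
    r <- (a_f - s_o) / denom
  } else {
    mat <- profiles[others, , drop = FALSE]
    rs <- sweep(-mat, 2, a_f, `+`) / sweep(mat, 2, a_f, `+`)
    skip <- apply(sweep(mat, 2, a_f, `+`) == 0, 2, any)
    if (any(skip))
      warnf("%d KO(s) with undefined per-ecosystem ratio; skipped",
            sum(skip))
    # least extreme per-ecosystem ratio: sign-consistent summary
    r <- apply(rs, 2, function(v) v[which.min(abs(v))])
    all_hi <- apply(rs, 2, function(v) all(v > cutoff))
    all_lo <- apply(rs, 2, function(v) all(v < -cutoff))
  }
  ko <- colnames(profiles)[!skip]
  r <- r[!skip]
  label <- if (method == "sum") {
    ifelse(r > cutoff, "enriched", ifelse(r < -cutoff, "reduced", "neither"))
  } else {
    ifelse(all_hi[!skip], "enriched",
           ifelse(all_lo[!skip], "reduced", "neither"))
  }
  data.frame(ko_id = ko, ratio = unname(r), label = unname(label),
             stringsAsFactors = FALSE)
}

#' Singleton / conserved classification of KOs
#'
#' A KO present (abundance > 0) in exactly one ecosystem is a
#' singleton; present in at least two it is conserved; KOs absent from
#' every ecosystem are dropped.
#'
#' @inheritParams prevalence_filter
#' @return data frame with `ko_id`, `n_ecosystems`, `label`.
#' @export
singleton_conserved <- function(profiles) {
  n_eco <- colSums(profiles > 0)
  keep <- n_eco > 0
  data.frame(ko_id = colnames(profiles)[keep],
             n_ecosystems = unname(n_eco[keep]),
             label = ifelse(n_eco[keep] == 1, "singleton", "conserved"),
             stringsAsFactors = FALSE)
}

#' Differential-KO report for a focal ecosystem
#'
#' Pipeline composition: normalize per-Mb profiles, keep prevalent
#' KOs, compute enrichment ratios, and return the enriched/reduced
#' rows ordered by |ratio| (descending) then KO id, with the
#' normalized abundance of each reported KO across all ecosystems
#' attached.
#'
#' @inheritParams normalize_profiles
#' @param focal single focal ecosystem to test.
#' @param exclude ecosystems excluded from the prevalence denominator
#'   (default: both supported focal classes present in the labels).
#' @param cutoff enrichment-ratio cutoff (default 0.9).
#' @param method ratio method, see [enrichment_ratio()].
#' @return list with `table` (differential KOs), `ratios` (all
#'   prevalent KOs), and `profiles`.
#' @export
differential_report <- function(counts, sizes, ecosystems, focal,
                                exclude = NULL, cutoff = 0.9,
                                method = "sum") {
  profiles <- normalize_profiles(counts, sizes, ecosystems)
  exclude <- exclude %||% intersect(
    c("Qilian Saline Lake sediment", "Tibet Freshwater Lake sediment"),
    rownames(profiles))
  exclude <- union(exclude, focal)
  prevalent <- prevalence_filter(profiles, focal = exclude)
  ratios <- enrichment_ratio(profiles[, prevalent, drop = FALSE],
                             focal = focal, cutoff = cutoff,
                             method = method)
  diff <- ratios[ratios$label != "neither", , drop = FALSE]
  diff <- diff[order(-abs(diff$ratio), diff$ko_id), , drop = FALSE]
  rownames(diff) <- NULL
  abund <- t(profiles[, diff$ko_id, drop = FALSE])
  list(table = cbind(diff, abund), ratios = ratios, profiles = profiles)
}
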