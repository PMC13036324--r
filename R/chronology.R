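# Divergence-time classification on time-calibrated trees, relative
# evolutionary distance, and the stratified MAG subsampler.

#' Node ages of a time-calibrated tree
#'
#' Branch lengths are in Ma and tips are extant (age 0); a node's age
#' is its path length to any descendant tip.  The tree must be
#' ultrametric within `tol` relative tolerance, otherwise an error
#' lists the offending tips.
#'
#' @param tree rooted `phylo` object with nonnegative branch lengths.
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return numeric vector of ages indexed by node number
#'   (tips 1..n, then internal nodes); tip ages are exactly 0.
#' @export
node_ages <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stopf("expected a 'phylo' tree")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch lengths")
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(n)])
  if (height <= 0) stopf("tree has zero height")
  off <- abs(depth[seq_len(n)] - height) / height > tol
  if (any(off))
    stopf("tree is not ultrametric; offending tip(s): %s",
          paste(tree$tip.label[off], collapse = ", "))
  ages <- height - depth
  ages[seq_len(n)] <- 0
  ages
}

#' Latest divergence time per tip
#'
#' The age (Ma) of each tip's immediate parent node -- the species'
#' most recent phylogenetic split.
#'
#' @inheritParams node_ages
#' @return named numeric vector, one entry per tip label.
#' @export
latest_divergence <- function(tree, tol = 1e-6) {
  ages <- node_ages(tree, tol)
  n <- ape::Ntip(tree)
  parent <- tree$edge[match(seq_len(n), tree$edge[, 2]), 1]
  setNames(ages[parent], tree$tip.label)
}

#' Classify species as possible ancient species (PAS) or extant
#'
#' PAS: latest divergence strictly before the eon boundary
#' (age > `boundary_ma`); ties at the boundary go to extant.
#' The default boundary is the Cryptozoic/Phanerozoic transition at
#' 541 Ma (some displays draw the line at 600 Ma; pass
#' `boundary_ma = 600` for that convention).
#'
#' @param latest_ages numeric vector of latest divergence ages (Ma).
#' @param boundary_ma eon boundary in Ma (default 541).
#' @return factor with levels `PAS`, `extant`, preserving names.
#' @export
classify_pas <- function(latest_ages, boundary_ma = 541) {
  if (boundary_ma <= 0) stopf("eon boundary must be positive")
  if (any(latest_ages < 0)) stopf("ages must be nonnegative")
  f <- factor(ifelse(latest_ages > boundary_ma, "PAS", "extant"),
              levels = c("PAS", "extant"))
  names(f) <- names(latest_ages)
  f
}

#' Habitat-group by eon summary of a PAS classification
#'
#' @param classification factor from [classify_pas()], named by
#'   species id.
#' @param groups named character vector mapping species id to habitat
#'   group (e.g. `Sediment only`, `Water only`, `Shared`).
#' @return list with `table` (group x eon counts) and `percent`
#'   (per-eon group percentages, 1 dp half-up; NA for empty eons).
#' @export
pas_group_summary <- function(classification, groups) {
  ids <- names(classification)
  missing <- ids[!ids %in% names(groups)]
  if (length(missing) > 0)
    stopf("species without habitat group: %s",
          paste(missing, collapse = ", "))
  g <- factor(groups[ids])
  tab <- table(group = g, eon = classification)
  tots <- colSums(tab)
  pct <- tab
  for (j in seq_along(tots)) {
    pct[, j] <- if (tots[j] > 0) percent(tab[, j], tots[j], 1) else NA_real_
  }
  list(table = tab, percent = pct)
}

#' Per-group proportion of species diverging at or before a given age
#'
#' For each habitat group and each threshold t on the grid, the
#' fraction of the group's species whose latest divergence age is
#' >= t.  At t = 0 every species counts, so curves end at 1.
#'
#' @param latest_ages named numeric vector of latest divergence ages.
#' @param groups named character vector of habitat groups.
#' @param grid numeric vector of age thresholds (Ma), strictly
#'   decreasing toward 0.
#' @return data frame with columns `group`, `age_ma`, `proportion`.
#' @export
proportion_curves <- function(latest_ages, groups, grid) {
  if (length(grid) > 1 && any(diff(grid) >= 0))
    stopf("grid must be strictly decreasing")
  ids <- names(latest_ages)
  g <- groups[ids]
  rows <- lapply(unique(g), function(grp) {
    a <- latest_ages[g == grp]
    if (length(a) == 0) {
      warnf("empty group '%s'; flat zero curve", grp)
      return(data.frame(group = grp, age_ma = grid, proportion = 0))
    }
    data.frame(group = grp, age_ma = grid,
               proportion = vapply(grid, function(t) mean(a >= t),
                                   numeric(1)))
  })
  do.call(rbind, rows)
}

#' Relative evolutionary distance (RED)
#'
#' RED interpolates node depth between 0 at the root and 1 at the
#' leaves: for a node n with parent p, branch length d, and u = d plus
#' the mean distance from n to its descendant leaves,
#' RED(n) = RED(p) + (d/u) (1 - RED(p)).  Leaves are assigned 1.
#'
#' @param tree rooted `phylo` with branch lengths (time or
#'   substitution units).
#' @return numeric vector of RED values indexed by node number.
#' @export
red <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("expected a 'phylo' tree")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  if (any(depth[seq_len(n)] <= 0))
    stopf("zero-length root-to-leaf path; RED undefined")
  tr <- ape::reorder.phylo(tree, "postorder")
  nl <- c(rep(1, n), rep(0, m))        # descendant leaf counts
  sumd <- numeric(n + m)               # summed node-to-leaf distances
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]; len <- tr$edge.length[i]
    nl[p] <- nl[p] + nl[ch]
    sumd[p] <- sumd[p] + sumd[ch] + len * nl[ch]
  }
  meand <- sumd / nl
  out <- rep(NA_real_, n + m)
  root <- n + 1
  out[root] <- 0
  for (i in rev(seq_len(nrow(tr$edge)))) {  # preorder
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]; len <- tr$edge.length[i]
    if (ch <= n) {
      out[ch] <- 1
    } else {
      u <- len + meand[ch]
      out[ch] <- out[p] + (len / u) * (1 - out[p])
    }
  }
  out
}

#' Stratified subsampling of a MAG table by phylum
#'
#' Phyla with fewer than `min_phylum` members are merged into a single
#' stratum; `n_target` MAGs are then drawn without replacement with
#' per-stratum allocation proportional to stratum size
#' (largest-remainder rounding), independently `reps` times.
#'
#' @param mag_ids character vector of MAG ids.
#' @param phyla character vector of phylum labels, same length.
#' @param n_target subsample size (default 200).
#' @param min_phylum minimum stratum size before merging (default 30).
#' @param reps number of independent subsamples (default 15).
#' @param seed RNG seed.
#' @param merged_label label of the merged stratum.
#' @return list of `reps` character vectors of MAG ids, with the
#'   allocation as attribute `allocation`.
#' @export
stratified_subsample <- function(mag_ids, phyla, n_target = 200,
                                 min_phylum = 30, reps = 15, seed = 1,
                                 merged_label = "merged") {
  if (length(mag_ids) != length(phyla)) stopf("ids and phyla differ in length")
  if (n_target > length(mag_ids))
    stopf("n_target (%d) exceeds table size (%d)", n_target, length(mag_ids))
  tab <- table(phyla)
  small <- names(tab)[tab < min_phylum]
  strata <- ifelse(phyla %in% small, merged_label, phyla)
  sizes <- table(strata)
  quota <- n_target * as.numeric(sizes) / length(mag_ids)
  base <- floor(quota)
  rem <- n_target - sum(base)
  frac <- quota - base
  add <- rep(0L, length(sizes))
  if (rem > 0) {
    ord <- order(-frac, -as.numeric(sizes), names(sizes))
    add[ord[seq_len(rem)]] <- 1L
  }
  alloc <- setNames(as.integer(base + add), names(sizes))
  with_stream(seed, "stratified_subsample", {
    draws <- lapply(seq_len(reps), function(r) {
      unlist(lapply(names(alloc), function(s) {
        pool <- mag_ids[strata == s]
        pool[sample.int(length(pool), alloc[[s]])]
      }), use.names = FALSE)
    })
    attr(draws, "allocation") <- alloc
    draws
  })
}
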