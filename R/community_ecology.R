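# Diversity, ordination, distance-decay, and Sloan neutral-community
# model fitting.

#' Shannon diversity (nats)
#'
#' @param x nonnegative abundance vector with at least one positive
#'   entry; normalized internally.
#' @return H = -sum p_i log p_i over positive entries, in nats.
#' @export
#' @examples
#' shannon(c(0.5, 0.25, 0.25))  # 1.0397...
shannon <- function(x) {
  if (any(x < 0)) stopf("abundances must be nonnegative")
  s <- sum(x)
  if (s == 0) stopf("all-zero abundance vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' sum |x_i - y_i| / sum (x_i + y_i).  Similarity is 1 minus this.
#'
#' @param x,y equal-length nonnegative vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
#' @examples
#' bray_curtis(c(2, 2), c(1, 3))  # 0.25
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stopf("abundances must be nonnegative")
  denom <- sum(x + y)
  if (denom == 0) stopf("both vectors are all-zero")
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis similarity matrix
#'
#' @param abund samples x taxa abundance matrix (rows = samples).
#' @return symmetric matrix of similarities (1 - dissimilarity).
#' @export
bray_curtis_similarity <- function(abund) {
  d <- as.matrix(vegan::vegdist(abund, method = "bray"))
  1 - d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Classical metric scaling on a symmetric dissimilarity matrix with a
#' zero diagonal.  Axes are ordered by descending eigenvalue; axes
#' belonging to negative eigenvalues are reported in `eig` but
#' dropped from the coordinates.
#'
#' @param d symmetric dissimilarity matrix, zero diagonal.
#' @param k number of axes requested (default 2); truncated with a
#'   warning when fewer positive eigenvalues exist.
#' @return list with `coordinates` (n x k' matrix) and `eig`
#'   (all eigenvalues, descending).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stopf("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("dissimilarity matrix must have a zero diagonal")
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = min(k, nrow(d) - 1),
                                   eig = TRUE))
  n_pos <- sum(fit$eig > 1e-10)
  if (k > n_pos) {
    warnf("requested %d axes but only %d positive eigenvalues; truncating",
          k, n_pos)
    k <- n_pos
  }
  list(coordinates = fit$points[, seq_len(k), drop = FALSE],
       eig = fit$eig)
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6,371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in km.
#' @export
#' @examples
#' haversine_km(0, 0, 90, 0)  # quarter meridian, 10007.54 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stopf("latitude outside [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180)) stopf("longitude outside [-180, 180]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Pairwise similarity/distance table for distance-decay analysis
#'
#' @param abund samples x taxa abundance matrix with row names.
#' @param geo data frame with columns `sample_id`, `latitude`,
#'   `longitude`, `elevation` covering all rows of `abund`.
#' @param kind `geographic` (haversine km) or `vertical`
#'   (absolute elevation difference, m).
#' @return data frame of unordered sample pairs with `distance` and
#'   Bray-Curtis `similarity`.
#' @export
ddr_pairs <- function(abund, geo, kind = c("geographic", "vertical")) {
  kind <- match.arg(kind)
  assert_cols(geo, c("sample_id", "latitude", "longitude", "elevation"),
              "sample geography")
  if (!all(rownames(abund) %in% geo$sample_id))
    stopf("samples missing from the geography table")
  geo <- geo[match(rownames(abund), geo$sample_id), ]
  sim <- bray_curtis_similarity(abund)
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  dist <- if (kind == "geographic") {
    haversine_km(geo$latitude[idx[, 1]], geo$longitude[idx[, 1]],
                 geo$latitude[idx[, 2]], geo$longitude[idx[, 2]])
  } else {
    abs(geo$elevation[idx[, 1]] - geo$elevation[idx[, 2]])
  }
  data.frame(sample_1 = rownames(abund)[idx[, 1]],
             sample_2 = rownames(abund)[idx[, 2]],
             distance = dist,
             similarity = sim[idx],
             stringsAsFactors = FALSE)
}

#' Distance-decay relationship fit
#'
#' Least-squares fit of log similarity on distance.  The default is the
#' power-law form (log similarity ~ log distance); `log_distance =
#' FALSE` fits the exponential form (log similarity ~ distance), whose
#' slope is minus the decay rate per km.  Pairs with zero distance or
#' zero similarity are excluded and counted.
#'
#' @param similarities,distances numeric vectors of equal length.
#' @param kind label stored in the fit (`geographic` or `vertical`).
#' @param log_distance logical; log-transform distance (default TRUE).
#' @return object of class `ddr_fit`: list with `slope`, `intercept`,
#'   `correlation`, `n_pairs`, `n_excluded`, `kind`, `log_distance`.
#' @export
ddr_fit <- function(similarities, distances,
                    kind = c("geographic", "vertical"),
                    log_distance = TRUE) {
  kind <- match.arg(kind)
  if (length(similarities) != length(distances))
    stopf("similarity and distance vectors differ in length")
  usable <- distances > 0 & similarities > 0 &
    is.finite(distances) & is.finite(similarities)
  n_excl <- sum(!usable)
  s <- similarities[usable]
  d <- distances[usable]
  if (length(s) < 3) stopf("fewer than 3 usable pairs (%d)", length(s))
  xx <- if (log_distance) log(d) else d
  fit <- lm(log(s) ~ xx)
  corr <- if (stats::sd(xx) > 0 && stats::sd(log(s)) > 0)
    stats::cor(xx, log(s)) else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 correlation = corr,
                 n_pairs = length(s),
                 n_excluded = n_excl,
                 kind = kind,
                 log_distance = log_distance),
            class = "ddr_fit")
}

#' @export
print.ddr_fit <- function(x, ...) {
  form <- if (x$log_distance) "ln(similarity) ~ ln(distance)"
          else "ln(similarity) ~ distance"
  cat(sprintf("Distance-decay fit (%s, %s)\n", x$kind, form))
  cat(sprintf("  slope       %.6g\n  intercept   %.4g\n", x$slope, x$intercept))
  cat(sprintf("  correlation %.3f\n  pairs used  %d (excluded %d)\n",
              x$correlation, x$n_pairs, x$n_excluded))
  invisible(x)
}

#' Sloan neutral community model prediction
#'
#' Predicted occurrence frequency of a taxon with mean relative
#' abundance `p` in a community of size `N` with migration rate `m`:
#' 1 - I_d(N m p, N m (1 - p)), the regularized incomplete beta
#' function evaluated at detection limit `d`.
#'
#' @param p mean relative abundances in (0, 1).
#' @param m migration rate in (0, 1].
#' @param N community size.
#' @param d detection limit (relative abundance).
#' @return predicted frequencies in \[0, 1\].
#' @export
ncm_predict <- function(p, m, N, d) {
  1 - pbeta(d, N * m * p, N * m * (1 - p))
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration rate `m` by nonlinear least squares of
#' observed occurrence frequencies on [ncm_predict()].  The coefficient
#' of determination R^2 = 1 - SSE/SST is unbounded below; strongly
#' non-neutral communities yield negative values.
#'
#' @param p mean relative abundances in (0, 1), >= 10 taxa.
#' @param freq observed occurrence frequencies in \[0, 1\].
#' @param N community size (e.g. mean read count per sample).
#' @param d detection limit; default 1/N.
#' @return object of class `ncm_fit`: list with `m`, `N`, `d`,
#'   `r_squared`, `converged`, and on failure a `message`.
#' @export
ncm_fit <- function(p, freq, N, d = NULL) {
  if (length(p) != length(freq)) stopf("p and freq differ in length")
  if (length(p) < 10) stopf("need at least 10 taxa to fit the model")
  if (any(p <= 0 | p >= 1)) stopf("mean relative abundances must be in (0, 1)")
  if (any(freq < 0 | freq > 1)) stopf("frequencies must be in [0, 1]")
  d <- d %||% (1 / N)
  fit <- tryCatch(
    minpack.lm::nlsLM(freq ~ ncm_predict(p, m, N, d),
                      start = list(m = 0.5),
                      lower = 1e-9, upper = 1,
                      control = nls.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(m = NA_real_, N = N, d = d,
                          r_squared = NA_real_, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "ncm_fit"))
  }
  m_hat <- unname(coef(fit)[["m"]])
  pred <- ncm_predict(p, m_hat, N, d)
  sse <- sum((freq - pred)^2)
  sst <- sum((freq - mean(freq))^2)
  structure(list(m = m_hat, N = N, d = d,
                 r_squared = 1 - sse / sst, converged = TRUE),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Neutral community model fit FAILED:", x$message, "\n")
  } else {
    cat(sprintf("Neutral community model: m = %.4g, N = %.4g, R^2 = %.3f\n",
                x$m, x$N, x$r_squared))
  }
  invisible(x)
}

#' Goodness-of-fit R^2 of a frequency curve against the neutral model
#'
#' Convenience for evaluating a fixed (m, N) rather than fitting.
#'
#' @inheritParams ncm_fit
#' @param m migration rate to evaluate.
#' @return R^2 (may be negative).
#' @export
ncm_r_squared <- function(p, freq, m, N, d = NULL) {
  d <- d %||% (1 / N)
  pred <- ncm_predict(p, m, N, d)
  1 - sum((freq - pred)^2) / sum((freq - mean(freq))^2)
}

#' Group comparison with BH correction
#'
#' Kruskal-Wallis across all groups plus two-sided pairwise
#' Mann-Whitney tests with Benjamini-Hochberg adjustment.
#' Significance is called at adjusted p < 0.05.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, >= 2 nonempty groups.
#' @return list with `kruskal_p` and a `pairwise` data frame
#'   (`group_1`, `group_2`, `p`, `p_adjusted`, `significant`).
#' @export
group_stats <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stopf("need at least 2 groups")
  if (any(tab < 1)) stopf("every group needs at least one observation")
  kp <- kruskal.test(values, factor(groups))$p.value
  gs <- names(tab)
  pairs <- utils::combn(gs, 2)
  pw <- apply(pairs, 2, function(pr) {
    suppressWarnings(
      wilcox.test(values[groups == pr[1]], values[groups == pr[2]],
                  alternative = "two.sided")$p.value)
  })
  adj <- p.adjust(pw, method = "BH")
  list(kruskal_p = kp,
       pairwise = data.frame(group_1 = pairs[1, ], group_2 = pairs[2, ],
                             p = pw, p_adjusted = adj,
                             significant = adj < 0.05,
                             stringsAsFactors = FALSE))
}
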