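# Seeded generators for every input the pipeline consumes, each with
# planted, machine-readable ground truth.  One documented RNG stream
# per artifact (derived from the single config seed), so artifacts are
# independently reproducible.

#' Simulation configuration
#'
#' Single container of all generator parameters.  The same
#' configuration always yields byte-identical artifacts.
#'
#' @param seed master integer seed; every generator derives its own
#'   stream from it.
#' @param n_tips,n_samples,n_species,n_mags,n_kos,n_bgcs problem sizes.
#' @param ancient_fraction planted fraction of tips whose parent node
#'   is older than the eon boundary, in \[0, 1\].
#' @param ddr_lambda planted distance-decay rate per km (>= 0; 0 gives
#'   a flat similarity profile).
#' @param ncm_m planted neutral-model migration rate in (0, 1].
#' @param ncm_N planted neutral-model community size (>= 100).
#' @param enriched_kos KO ids planted as enriched in the focal
#'   ecosystem.
#' @param reduced_kos KO ids planted as reduced.
#' @param novel_bgc_fraction planted fraction of novel GCFs in \[0, 1\].
#' @param tier_counts named integer vector `c(high=, medium=, fail=)`
#'   of planted MIMAG tier counts.
#' @param ddr_noise_sd lognormal abundance noise (sd of log), default
#'   0.05.
#' @param ncm_noise `"binomial"` (per-sample detection draws) or
#'   `"none"` (frequencies exactly on the model curve).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tips = 200L, n_samples = 50L, n_species = 500L,
                       n_mags = 100L, n_kos = 200L, n_bgcs = 300L,
                       ancient_fraction = 0.4,
                       ddr_lambda = 0.002,
                       ncm_m = 0.1, ncm_N = 1000L,
                       enriched_kos = c("K00978", "K01709"),
                       reduced_kos = "K10947",
                       novel_bgc_fraction = 0.5,
                       tier_counts = c(high = 10L, medium = 50L, fail = 40L),
                       ddr_noise_sd = 0.05,
                       ncm_noise = c("binomial", "none")) {
  ncm_noise <- match.arg(ncm_noise)
  if (ancient_fraction < 0 || ancient_fraction > 1)
    stopf("ancient_fraction must be in [0, 1]")
  if (ddr_lambda < 0) stopf("ddr_lambda must be nonnegative")
  if (ncm_m <= 0 || ncm_m > 1) stopf("ncm_m must be in (0, 1]")
  if (ncm_N < 100) stopf("ncm_N must be >= 100")
  if (novel_bgc_fraction < 0 || novel_bgc_fraction > 1)
    stopf("novel_bgc_fraction must be in [0, 1]")
  if (any(tier_counts < 0)) stopf("negative tier counts")
  if (!all(c("high", "medium", "fail") %in% names(tier_counts)))
    stopf("tier_counts needs 'high', 'medium' and 'fail'")
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 n_samples = as.integer(n_samples),
                 n_species = as.integer(n_species),
                 n_mags = as.integer(n_mags), n_kos = as.integer(n_kos),
                 n_bgcs = as.integer(n_bgcs),
                 ancient_fraction = ancient_fraction,
                 ddr_lambda = ddr_lambda,
                 ncm_m = ncm_m, ncm_N = as.integer(ncm_N),
                 enriched_kos = enriched_kos, reduced_kos = reduced_kos,
                 novel_bgc_fraction = novel_bgc_fraction,
                 tier_counts = tier_counts,
                 ddr_noise_sd = ddr_noise_sd, ncm_noise = ncm_noise),
            class = "sim_config")
}

EON_BOUNDARY_MA <- 541

#' Simulate a time-calibrated tree with planted ancient tips
#'
#' Draws a coalescent tree and rescales branch lengths so that a
#' planted fraction of tips has a parent node older than 541 Ma.  Each
#' tip receives a habitat group (Sediment only / Water only / Shared).
#' The realized ancient fraction (recorded in the truth sidecar) can
#' deviate from the target by at most one cherry when parent ages tie.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_time_tree`: list with `tree` (`phylo`,
#'   branch lengths in Ma), `groups` (tip habitat table), and `truth`
#'   (planted PAS tip set, realized fraction, scale factor).
#' @export
gen_time_tree <- function(config) {
  n <- config$n_tips
  if (n < 3) stopf("n_tips must be >= 3")
  f <- config$ancient_fraction
  with_stream(config$seed, "time_tree", {
    tree <- ape::rcoal(n, tip.label = sprintf("sp%04d", seq_len(n)))
    depth <- ape::node.depth.edgelength(tree)
    height <- max(depth[seq_len(n)])
    ages <- height - depth
    parent <- tree$edge[match(seq_len(n), tree$edge[, 2]), 1]
    pa <- ages[parent]                       # per-tip parent ages
    k <- round(f * n)
    s <- if (k == 0) {
      0.5 * EON_BOUNDARY_MA / max(pa)
    } else if (k == n) {
      2 * EON_BOUNDARY_MA / min(pa)
    } else {
      a <- sort(pa, decreasing = TRUE)
      EON_BOUNDARY_MA / ((a[k] + a[k + 1]) / 2)
    }
    tree$edge.length <- tree$edge.length * s
    # bookkeep planted labels from the scaled tree itself so the truth
    # is exact under floating point
    pa <- latest_divergence(tree)
    planted <- names(pa)[pa > EON_BOUNDARY_MA]
    groups <- data.frame(
      species_id = tree$tip.label,
      group = sample(c("Sediment only", "Water only", "Shared"), n,
                     replace = TRUE, prob = c(0.45, 0.40, 0.15)),
      stringsAsFactors = FALSE)
    structure(list(tree = tree, groups = groups,
                   truth = list(planted_pas = planted,
                                realized_ancient_fraction = length(planted) / n,
                                target_ancient_fraction = f,
                                boundary_ma = EON_BOUNDARY_MA,
                                scale = s)),
              class = "sim_time_tree")
  })
}

#' Simulate a MAG metadata table with exact planted MIMAG tier counts
#'
#' Completeness, contamination, rRNA presence and tRNA counts are
#' drawn inside each tier's defining region, so [mimag_tier()] recovers
#' the planted counts exactly.  Region/ecosystem/site labels and a
#' species clustering (for exclusivity summaries) are attached.
#'
#' @param config a [sim_config()]; `tier_counts` fixes the plant.
#' @return object of class `sim_mag_table`: list with `mags` (record
#'   table) and `truth` (planted tier per MAG id).
#' @export
gen_mag_table <- function(config) {
  tc <- config$tier_counts
  n <- sum(tc)
  if (n < 1) stopf("empty tier plan")
  with_stream(config$seed, "mag_table", {
    draw_tier <- function(tier, count) {
      if (count == 0) return(NULL)
      switch(tier,
        high = data.frame(
          completeness = runif(count, 91, 99.5),
          contamination = runif(count, 0, 4.5),
          has_rrna_5s = TRUE, has_rrna_16s = TRUE, has_rrna_23s = TRUE,
          n_trna = sample(18:45, count, replace = TRUE)),
        medium = data.frame(
          # completeness capped at 90 so the high tier is unreachable
          completeness = runif(count, 50, 90),
          contamination = runif(count, 0, 9.5),
          has_rrna_5s = sample(c(TRUE, FALSE), count, replace = TRUE),
          has_rrna_16s = sample(c(TRUE, FALSE), count, replace = TRUE),
          has_rrna_23s = sample(c(TRUE, FALSE), count, replace = TRUE),
          n_trna = sample(0:30, count, replace = TRUE)),
        fail = {
          lowc <- rbinom(count, 1, 0.5) == 1
          data.frame(
            completeness = ifelse(lowc, runif(count, 15, 49.5),
                                  runif(count, 50, 95)),
            contamination = ifelse(lowc, runif(count, 0, 9),
                                   runif(count, 10.5, 25)),
            has_rrna_5s = sample(c(TRUE, FALSE), count, replace = TRUE),
            has_rrna_16s = sample(c(TRUE, FALSE), count, replace = TRUE),
            has_rrna_23s = sample(c(TRUE, FALSE), count, replace = TRUE),
            n_trna = sample(0:30, count, replace = TRUE))
        })
    }
    parts <- mapply(draw_tier, c("high", "medium", "fail"),
                    tc[c("high", "medium", "fail")], SIMPLIFY = FALSE)
    mags <- do.call(rbind, parts)
    tier <- rep(c("high", "medium", "fail"),
                tc[c("high", "medium", "fail")])
    ord <- sample.int(n)
    mags <- mags[ord, , drop = FALSE]
    tier <- tier[ord]
    region <- sample(c("Tibet", "Qilian"), n, replace = TRUE,
                     prob = c(0.7, 0.3))
    ecosystem <- ifelse(
      region == "Tibet",
      sample(c("River", "Saline Lake", "Wetland", "Freshwater Lake"), n,
             replace = TRUE, prob = c(0.13, 0.12, 0.51, 0.24)),
      sample(c("River", "Saline Lake", "Wetland"), n, replace = TRUE,
             prob = c(0.32, 0.52, 0.16)))
    site <- paste0(substr(region, 1, 1), "_",
                   gsub(" ", "", ecosystem), "_",
                   sample(1:3, n, replace = TRUE))
    # skewed species sizes: some clusters collect several MAGs
    n_sp <- max(1, round(0.6 * n))
    species <- sprintf("cl%04d", sample.int(n_sp, n, replace = TRUE,
                                            prob = 1 / seq_len(n_sp)))
    mags <- data.frame(
      mag_id = sprintf("mag%05d", seq_len(n)),
      sample_id = paste0("S", sample(1:max(2, round(n / 3)), n, replace = TRUE)),
      species_id = species,
      region = region, ecosystem = ecosystem, site_id = site,
      mags,
      strain_heterogeneity = runif(n, 0, 20),
      genome_size = round(runif(n, 1.5e6, 6e6)),
      gc = runif(n, 0.35, 0.65),
      stringsAsFactors = FALSE)
    rownames(mags) <- NULL
    structure(list(mags = mags,
                   truth = list(tiers = setNames(tier, mags$mag_id),
                                tier_counts = as.list(tc))),
              class = "sim_mag_table")
  })
}

#' Simulate a community with a planted distance-decay rate
#'
#' Samples are placed on a west-east transect at constant latitude.
#' Walking the transect, each community is an exp(-lambda d) mixture
#' of its neighbor and a fresh block of species disjoint from all
#' earlier blocks, which makes the noise-free pairwise Bray-Curtis
#' similarity exactly exp(-lambda d).  Lognormal abundance noise
#' (sd `ddr_noise_sd` on the log scale) is applied afterwards.
#' Elevation increases along the transect, so vertical distance decays
#' similarity as well.
#'
#' @param config a [sim_config()]; `ddr_lambda` is the planted decay
#'   rate per km.
#' @return object of class `sim_ddr`: list with `abundance`
#'   (samples x species, TPM-like scale), `geo` (sample coordinates),
#'   and `truth` (lambda, noise model).
#' @export
gen_ddr_community <- function(config) {
  n <- config$n_samples
  if (n < 4) stopf("n_samples must be >= 4")
  lambda <- config$ddr_lambda
  with_stream(config$seed, "ddr_community", {
    # south-north transect at constant longitude: great-circle
    # distances along a meridian are exactly additive, so the chain
    # mixing below yields exactly exp(-lambda d) for every pair
    lat <- sort(runif(n, 29, 38))
    lon <- rep(90, n)
    elev <- 3000 + 1200 * (lat - 29) / 9 + rnorm(n, 0, 25)
    block <- max(5, floor(config$n_species / n))
    n_sp <- block * n
    fresh <- function(i) {
      v <- numeric(n_sp)
      idx <- ((i - 1) * block + 1):(i * block)
      a <- rlnorm(block, 0, 1)
      v[idx] <- a / sum(a)
      v
    }
    comm <- matrix(0, n, n_sp)
    comm[1, ] <- fresh(1)
    for (i in 2:n) {
      d <- haversine_km(lat[i - 1], lon[i - 1], lat[i], lon[i])
      a <- exp(-lambda * d)
      comm[i, ] <- a * comm[i - 1, ] + (1 - a) * fresh(i)
    }
    noise <- matrix(exp(rnorm(n * n_sp, 0, config$ddr_noise_sd)), n, n_sp)
    abund <- comm * noise * 1e6
    rownames(abund) <- sprintf("S%03d", seq_len(n))
    colnames(abund) <- sprintf("sp%05d", seq_len(n_sp))
    geo <- data.frame(sample_id = rownames(abund), latitude = lat,
                      longitude = lon, elevation = elev,
                      stringsAsFactors = FALSE)
    structure(list(abundance = abund, geo = geo,
                   truth = list(lambda = lambda,
                                noise = "lognormal",
                                noise_sd = config$ddr_noise_sd)),
              class = "sim_ddr")
  })
}

#' Simulate occurrence-frequency data under the Sloan neutral model
#'
#' Mean relative abundances are lognormal; each species' detection
#' frequency is its neutral-model prediction at the planted (N, m)
#' with detection limit 1/N, observed either exactly
#' (`ncm_noise = "none"`) or through per-sample binomial detection
#' draws over `n_samples` samples.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_ncm`: list with `data` (species_id,
#'   p, freq) and `truth` (m, N, d, noise model).
#' @export
gen_ncm_data <- function(config) {
  if (config$n_species < 50) stopf("n_species must be >= 50")
  N <- config$ncm_N
  m <- config$ncm_m
  with_stream(config$seed, "ncm", {
    x <- rlnorm(config$n_species, 0, 1.5)
    p <- x / sum(x)
    d <- 1 / N
    tf <- ncm_predict(p, m, N, d)
    freq <- if (config$ncm_noise == "none") tf else
      rbinom(config$n_species, config$n_samples, tf) / config$n_samples
    structure(list(
      data = data.frame(species_id = sprintf("sp%04d", seq_along(p)),
                        p = p, freq = freq, stringsAsFactors = FALSE),
      truth = list(m = m, N = N, d = d, noise = config$ncm_noise,
                   n_samples = config$n_samples)),
      class = "sim_ncm")
  })
}

KO_ECOSYSTEMS <- c(
  "Qilian Saline Lake sediment", "Tibet Freshwater Lake sediment",
  "Marine sediment", "Marine water", "Hydrothermal sediment",
  "Cold seep sediment", "Saline Lake sediment (coast)",
  "Estuary sediment", "Hot spring sediment", "Permafrost soil",
  "Lake sediment (temperate)", "River sediment (lowland)",
  "Wetland soil", "Deep sea sediment", "Mangrove sediment",
  "Soda lake sediment")

#' Simulate a MAG x KO count matrix with planted differential KOs
#'
#' Sixteen habitat classes (two focal plateau classes plus fourteen
#' references).  Planted enriched KOs are abundant in the focal
#' ecosystem and present at trace level in five non-focal ecosystems
#' (so they pass the prevalence filter and exceed ratio 0.9 by
#' construction); planted reduced KOs are absent from the focal
#' ecosystem but widespread elsewhere; one KO is planted as a
#' singleton.  Broad background KOs are present in every ecosystem at
#' comparable per-Mb abundance, keeping their ratios far from +0.9.
#'
#' @param config a [sim_config()]; `enriched_kos` / `reduced_kos` fix
#'   the plant; `n_kos` sets the total KO count.
#' @return object of class `sim_ko`: list with `counts` (MAG x KO),
#'   `sizes` (Mb), `ecosystems` (label per MAG), and `truth`.
#' @export
gen_ko_matrix <- function(config) {
  ecos <- KO_ECOSYSTEMS
  if (length(ecos) < 2) stopf("need at least 2 ecosystems")
  focal <- ecos[1]
  nonfocal <- ecos[-(1:2)]
  per_eco <- 5
  with_stream(config$seed, "ko_matrix", {
    mag_eco <- rep(ecos, each = per_eco)
    n_mag <- length(mag_eco)
    mag_id <- sprintf("mag%03d", seq_len(n_mag))
    sizes <- setNames(runif(n_mag, 1.5, 4.5), mag_id)
    singleton_ko <- "K99901"
    planted <- c(config$enriched_kos, config$reduced_kos, singleton_ko)
    n_bg <- max(0, config$n_kos - length(planted))
    bg_ids <- sprintf("K%05d", sample(setdiff(10000:99899,
      as.integer(sub("K", "", planted[grepl("^K[0-9]+$", planted)]))),
      n_bg))
    n_broad <- round(0.7 * n_bg)
    broad <- bg_ids[seq_len(n_broad)]
    sparse <- setdiff(bg_ids, broad)
    kos <- c(planted, bg_ids)
    counts <- matrix(0L, n_mag, length(kos),
                     dimnames = list(mag_id, kos))
    # broad background: every ecosystem, stable per-KO base count
    for (ko in broad) {
      b <- sample(5:20, 1)
      counts[, ko] <- pmax(0L, b + sample(-1:1, n_mag, replace = TRUE))
    }
    # sparse background: <= 4 non-focal ecosystems -> never prevalent
    for (ko in sparse) {
      in_eco <- sample(nonfocal, sample(1:4, 1))
      rows <- mag_eco %in% in_eco
      counts[rows, ko] <- rpois(sum(rows), 3)
    }
    # enriched: strong in focal, trace presence in 5 non-focal
    for (ko in config$enriched_kos) {
      counts[mag_eco == focal, ko] <- sample(80:120, per_eco, replace = TRUE)
      trace_eco <- sample(nonfocal, 5)
      for (e in trace_eco) {
        rows <- which(mag_eco == e)
        counts[sample(rows, 1), ko] <- 1L
      }
    }
    # reduced: absent in focal, widespread elsewhere
    for (ko in config$reduced_kos) {
      in_eco <- sample(nonfocal, 10)
      rows <- mag_eco %in% in_eco
      counts[rows, ko] <- rpois(sum(rows), 5) + 1L
    }
    # singleton: one non-focal ecosystem only
    counts[mag_eco == sample(nonfocal, 1), singleton_ko] <-
      rpois(per_eco, 4) + 1L
    structure(list(counts = counts, sizes = sizes,
                   ecosystems = setNames(mag_eco, mag_id),
                   truth = list(focal = focal,
                                enriched = config$enriched_kos,
                                reduced = config$reduced_kos,
                                singleton = singleton_ko)),
              class = "sim_ko")
  })
}

#' Simulate a BGC catalog with planted GCF/GCC novelty
#'
#' BGCs are assigned to GCFs (nested in GCCs); a planted fraction of
#' GCFs is novel.  Member mapped/unmapped status is drawn so each
#' GCF's mapped fraction falls strictly below 0.2 (novel) or at/above
#' 0.4 (not novel), making group classification exact by construction.
#' Gene-level abundances across 12 samples form three planted sample
#' blobs with distinct GCC profiles for the Ward-clustering stage.
#'
#' @param config a [sim_config()]; `novel_bgc_fraction` fixes the
#'   planted novel-GCF fraction; `n_bgcs` the catalog size.
#' @return object of class `sim_bgc`: list with `records` (BGC table,
#'   incl. gcf/gcc ids and membership values), `gene_abund`
#'   (gene x sample abundances in long layout), and `truth`.
#' @export
gen_bgc_catalog <- function(config) {
  n_bgc <- config$n_bgcs
  with_stream(config$seed, "bgc_catalog", {
    n_gcf <- max(3, round(n_bgc / 3))
    n_gcc <- max(3, round(n_gcf / 5))
    gcf_of_bgc <- sample.int(n_gcf, n_bgc, replace = TRUE)
    gcc_of_gcf <- sample.int(n_gcc, n_gcf, replace = TRUE)
    present <- sort(unique(gcf_of_bgc))
    n_novel <- round(config$novel_bgc_fraction * length(present))
    novel_gcfs <- sample(present, n_novel)
    mapped <- logical(n_bgc)
    for (g in present) {
      idx <- which(gcf_of_bgc == g)
      gsz <- length(idx)
      n_map <- if (g %in% novel_gcfs) {
        hi <- ceiling(0.2 * gsz) - 1
        if (hi < 0) 0L else sample(0:hi, 1)
      } else {
        sample(ceiling(0.4 * gsz):gsz, 1)
      }
      if (n_map > 0) mapped[sample(idx, n_map)] <- TRUE
    }
    membership <- ifelse(mapped, runif(n_bgc, 0, 900),
                         ifelse(runif(n_bgc) < 0.7,
                                runif(n_bgc, 901, 1500), NA))
    cats <- sample(BGC_CATEGORIES, n_bgc, replace = TRUE,
                   prob = c(0.08, 0.07, 0.12, 0.23, 0.05, 0.28, 0.07, 0.10))
    n_species <- max(2, round(n_bgc / 4))
    species <- sprintf("sp%04d", sample.int(n_species, n_bgc, replace = TRUE))
    len <- round(runif(n_bgc, 5000, 80000))
    records <- data.frame(
      bgc_id = sprintf("bgc%05d", seq_len(n_bgc)),
      mag_id = paste0("mag_", species),
      species_id = species,
      category = cats,
      length = len,
      contig_length = len + round(runif(n_bgc, 0, 50000)),
      gcf_id = sprintf("GCF%04d", gcf_of_bgc),
      gcc_id = sprintf("GCC%03d", gcc_of_gcf[gcf_of_bgc]),
      membership = membership,
      stringsAsFactors = FALSE)
    # 3 planted sample blobs with distinct per-GCC abundance profiles
    n_samp <- 12
    blob <- rep(1:3, each = n_samp / 3)
    samp_id <- sprintf("S%02d", seq_len(n_samp))
    gcc_base <- matrix(rlnorm(n_gcc * 3, 2, 1.2), n_gcc, 3)
    gene_rows <- lapply(seq_len(n_bgc), function(i) {
      ng <- sample(3:9, 1)
      base <- gcc_base[gcc_of_gcf[gcf_of_bgc[i]], blob]
      ab <- matrix(rep(base, each = ng) *
                     exp(rnorm(ng * n_samp, 0, 0.2)), ng, n_samp)
      df <- data.frame(gene_id = sprintf("%s_g%02d", records$bgc_id[i],
                                         seq_len(ng)),
                       bgc_id = records$bgc_id[i],
                       stringsAsFactors = FALSE)
      cbind(df, as.data.frame(setNames(as.data.frame(ab), samp_id)))
    })
    gene_abund <- do.call(rbind, gene_rows)
    gcf_truth <- do.call(rbind, lapply(present, function(g) {
      idx <- gcf_of_bgc == g
      data.frame(gcf_id = sprintf("GCF%04d", g),
                 mapped_fraction = mean(mapped[idx]),
                 novel = g %in% novel_gcfs, stringsAsFactors = FALSE)
    }))
    gcc_truth <- do.call(rbind, lapply(sort(unique(gcc_of_gcf[gcf_of_bgc])),
      function(cc) {
        idx <- gcc_of_gcf[gcf_of_bgc] == cc
        data.frame(gcc_id = sprintf("GCC%03d", cc),
                   mapped_fraction = mean(mapped[idx]),
                   novel = mean(mapped[idx]) < 0.4, stringsAsFactors = FALSE)
      }))
    structure(list(records = records, gene_abund = gene_abund,
                   truth = list(bgc_novel = !mapped,
                                gcf = gcf_truth, gcc = gcc_truth,
                                sample_blobs = setNames(blob, samp_id))),
              class = "sim_bgc")
  })
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a probe-design target genome and off-target genomes
#'
#' The target genome is random DNA; a handful of its 30-bp windows
#' (aligned to the 15-bp window grid) are copied verbatim into the
#' off-target genomes (planted *shared* windows, which the specificity
#' filter must remove) and another handful is recorded as planted
#' *unique* windows (which must survive).  All other windows are
#' unique with overwhelming probability (a 27/30-base chance match in
#' a few kb of random sequence).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_probe`: list with `target`
#'   (DNAStringSet), `offtargets` (DNAStringSet, names
#'   `genus|contig`), and `truth` (planted window tables).
#' @export
gen_probe_genomes <- function(config) {
  with_stream(config$seed, "probe_genomes", {
    contig_len <- 1800
    target_seqs <- c(t_contig1 = random_dna(contig_len),
                     t_contig2 = random_dna(contig_len))
    off_names <- c("genusA|contigA1", "genusB|contigB1", "genusC|contigC1")
    off_seqs <- setNames(vapply(off_names, function(i) random_dna(2000),
                                character(1)), off_names)
    starts_grid <- seq(0, contig_len - 30, by = 15)
    # non-overlapping planted windows, alternating unique/shared
    picked <- sort(sample(starts_grid[starts_grid %% 45 == 0], 8))
    plant <- data.frame(
      contig = rep(c("t_contig1", "t_contig2"), each = 4),
      start = c(picked[1:4], picked[5:8]),
      kind = rep(c("unique", "shared"), 4),
      stringsAsFactors = FALSE)
    plant$sequence <- vapply(seq_len(nrow(plant)), function(i) {
      substr(target_seqs[[plant$contig[i]]], plant$start[i] + 1,
             plant$start[i] + 30)
    }, character(1))
    shared <- plant[plant$kind == "shared", ]
    # non-repeating insertion slots per off-target so plants never
    # overwrite each other
    pos_pool <- lapply(off_names,
                       function(i) sample(seq(1, 2000 - 30, by = 40)))
    names(pos_pool) <- off_names
    for (i in seq_len(nrow(shared))) {
      dest <- off_names[((i - 1) %% length(off_names)) + 1]
      pos <- pos_pool[[dest]][1]
      pos_pool[[dest]] <- pos_pool[[dest]][-1]
      s <- off_seqs[[dest]]
      substr(s, pos, pos + 29) <- shared$sequence[i]
      off_seqs[[dest]] <- s
    }
    structure(list(target = Biostrings::DNAStringSet(target_seqs),
                   offtargets = Biostrings::DNAStringSet(off_seqs),
                   truth = list(planted = plant)),
              class = "sim_probe")
  })
}
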