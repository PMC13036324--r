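test_that("configuration validation rejects out-of-range plants", {
  expect_error(sim_config(ancient_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(ddr_lambda = -0.1), "nonnegative")
  expect_error(sim_config(ncm_m = 0), "\\(0, 1\\]")
  expect_error(sim_config(ncm_N = 50), ">= 100")
  expect_error(sim_config(tier_counts = c(high = -1, medium = 1, fail = 0)),
               "negative")
  expect_error(gen_time_tree(sim_config(n_tips = 2)), ">= 3")
  expect_error(gen_ddr_community(sim_config(n_samples = 3)), ">= 4")
  expect_error(gen_ncm_data(sim_config(n_species = 20)), ">= 50")
})

test_that("identical configurations give byte-identical artifacts", {
  cfg <- sim_config(seed = 42, n_tips = 40, n_samples = 10,
                    n_species = 100, n_bgcs = 60)
  gens <- list(gen_time_tree, gen_mag_table, gen_ddr_community,
               gen_ncm_data, gen_ko_matrix, gen_bgc_catalog,
               gen_probe_genomes)
  for (g in gens) {
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    sim_write(g(cfg), d1)
    sim_write(g(cfg), d2)
    expect_same_files(d1, d2)
  }
})

test_that("generator RNG streams leave global state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_time_tree(sim_config(seed = 9, n_tips = 10)))
  expect_identical(.Random.seed, before)
})

test_that("tree generator plants the ancient-tip fraction", {
  none <- gen_time_tree(sim_config(seed = 2, ancient_fraction = 0))
  expect_true(all(latest_divergence(none$tree) <= 541))
  expect_equal(length(none$truth$planted_pas), 0)
  all_anc <- gen_time_tree(sim_config(seed = 2, ancient_fraction = 1))
  cls <- classify_pas(latest_divergence(all_anc$tree))
  expect_true(all(cls == "PAS"))
  mid <- gen_time_tree(sim_config(seed = 3, n_tips = 200,
                                  ancient_fraction = 0.4))
  expect_lt(abs(mid$truth$realized_ancient_fraction - 0.4), 0.05)
  expect_true(ape::is.ultrametric(mid$tree, tol = 1e-6))
  expect_true(all(mid$groups$group %in%
                    c("Sediment only", "Water only", "Shared")))
})

test_that("MAG generator plants exact tier counts", {
  cfg <- sim_config(seed = 31, tier_counts = c(high = 7, medium = 23,
                                               fail = 12))
  sim <- gen_mag_table(cfg)
  tiers <- mimag_tier(sim$mags)
  expect_equal(as.integer(table(tiers)[c("high", "medium", "fail")]),
               c(7L, 23L, 12L))
  # generator bookkeeping agrees with the tiering stage, row by row
  expect_equal(as.character(tiers),
               unname(sim$truth$tiers[sim$mags$mag_id]))
})

test_that("DDR generator plants an exact exponential decay", {
  cfg0 <- sim_config(seed = 5, n_samples = 15, n_species = 150,
                     ddr_noise_sd = 0)
  sim <- gen_ddr_community(cfg0)
  pr <- ddr_pairs(sim$abundance, sim$geo, "geographic")
  expect_equal(pr$similarity, exp(-cfg0$ddr_lambda * pr$distance),
               tolerance = 1e-8)
  # lambda = 0: fitted slope's confidence interval covers zero
  flat <- gen_ddr_community(sim_config(seed = 5, ddr_lambda = 0))
  fp <- ddr_pairs(flat$abundance, flat$geo, "geographic")
  fit <- lm(log(similarity) ~ distance, data = fp[fp$distance > 0, ])
  ci <- confint(fit)["distance", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  # vertical distance decays too (elevation tracks the transect)
  pv <- ddr_pairs(sim$abundance, sim$geo, "vertical")
  fv <- ddr_fit(pv$similarity, pv$distance, kind = "vertical")
  expect_lt(fv$slope, 0)
})

test_that("NCM generator draws frequencies from the planted curve", {
  exact <- gen_ncm_data(sim_config(seed = 12, ncm_noise = "none"))
  expect_true(all(exact$data$freq >= 0 & exact$data$freq <= 1))
  expect_gte(ncm_r_squared(exact$data$p, exact$data$freq,
                           exact$truth$m, exact$truth$N, exact$truth$d),
             0.99)
  noisy <- gen_ncm_data(sim_config(seed = 12))
  expect_true(all(noisy$data$freq >= 0 & noisy$data$freq <= 1))
  expect_equal(noisy$truth$noise, "binomial")
})

test_that("emitted files parse through the package's own readers", {
  cfg <- sim_config(seed = 77, n_tips = 20, n_samples = 8,
                    n_species = 80, n_bgcs = 40)
  dir <- withr::local_tempdir()
  expect_no_warning({
    sim_write(gen_mag_table(cfg), file.path(dir, "mags"))
    mags <- read_mag_table(file.path(dir, "mags", "mags.tsv"))
    sim_write(gen_ddr_community(cfg), file.path(dir, "ddr"))
    ab <- read_matrix_tsv(file.path(dir, "ddr", "abundance.tsv"))
    geo <- read_sample_geo(file.path(dir, "ddr", "geo.tsv"))
    sim_write(gen_time_tree(cfg), file.path(dir, "tree"))
    tr <- ape::read.tree(file.path(dir, "tree", "tree.nwk"))
    sim_write(gen_probe_genomes(cfg), file.path(dir, "probe"))
    fa <- Biostrings::readDNAStringSet(file.path(dir, "probe",
                                                 "target.fasta"))
    truth <- read_truth_json(file.path(dir, "tree", "truth.json"))
  })
  expect_equal(nrow(mags), sum(cfg$tier_counts))
  expect_s3_class(mimag_tier(mags), "factor")
  expect_equal(dim(ab), c(8, 80))
  expect_equal(nrow(geo), 8)
  expect_equal(ape::Ntip(tr), 20)
  expect_length(fa, 2)
  expect_equal(truth$boundary_ma, 541)
  # round-tripped tree still classifies identically
  cls_rt <- classify_pas(latest_divergence(tr))
  expect_setequal(names(cls_rt)[cls_rt == "PAS"], unlist(truth$planted_pas))
})

test_that("probe generator leaves all windows when off-targets are absent", {
  sim <- gen_probe_genomes(sim_config(seed = 3))
  cand <- sliding_windows(sim$target)
  kept <- cross_set_uniqueness(cand, Biostrings::DNAStringSet(), "target")
  expect_equal(nrow(kept), nrow(cand))
})
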