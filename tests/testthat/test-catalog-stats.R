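test_that("quality score follows the completeness - 5*contamination rule", {
  expect_equal(quality_score(50, 0), 50)
  expect_equal(quality_score(75.9, 3.5), 58.4)
  expect_equal(quality_score(100, 20), 0)
  expect_lt(quality_score(60, 15), 0)
  # linearity: a completeness shift moves the score by exactly that much
  for (delta in c(0.1, 1, 7.3)) {
    expect_equal(quality_score(60 + delta, 4) - quality_score(60, 4), delta)
  }
  expect_error(quality_score(NA, 1), "missing")
  expect_error(quality_score(101, 0), "\\[0, 100\\]")
  expect_error(quality_score(90, -1), ">= 0")
})

test_that("MIMAG tiering partitions records and honors every clause", {
  rec <- function(comp, cont, rrna = TRUE, trna = 20) {
    data.frame(completeness = comp, contamination = cont,
               has_rrna_5s = rrna, has_rrna_16s = rrna,
               has_rrna_23s = rrna, n_trna = trna)
  }
  expect_equal(as.character(mimag_tier(rec(95, 2))), "high")
  expect_equal(as.character(mimag_tier(rec(95, 2, trna = 17))), "medium")
  expect_equal(as.character(mimag_tier(rec(95, 2, rrna = FALSE))), "medium")
  expect_equal(as.character(mimag_tier(rec(49.9, 1))), "fail")
  expect_equal(as.character(mimag_tier(rec(90, 2))), "medium")   # needs > 90
  expect_equal(as.character(mimag_tier(rec(50, 9.99))), "medium")
  expect_equal(as.character(mimag_tier(rec(95, 10))), "fail")

  # partition + high-implies-medium on a generated catalog
  sim <- gen_mag_table(sim_config(seed = 11))
  tiers <- mimag_tier(sim$mags)
  expect_false(any(is.na(tiers)))
  expect_equal(length(tiers), nrow(sim$mags))
  hi <- sim$mags[tiers == "high", ]
  expect_true(all(hi$completeness >= 50 & hi$contamination < 10))
})

test_that("eukaryotic flagging uses the inclusive 60% window rule", {
  expect_true(flag_eukaryotic(rep(c("eukaryote", "prokaryote"), c(6, 4))))
  expect_false(flag_eukaryotic(rep(c("eukaryote", "prokaryote"), c(5, 5))))
  expect_false(flag_eukaryotic(rep("prokaryote", 10)))
  expect_warning(res <- flag_eukaryotic(character(0)), "zero windows")
  expect_false(res)
  expect_error(flag_eukaryotic(c("eukaryote", "plant")), "unknown")
})

test_that("sub-contig window count matches brute-force enumeration", {
  lengths <- c(0:10, 499, 500, 999, 1000, 1001, 1499, 1500, 1501,
               seq(0, 10000, by = 7))
  expect_equal(contig_window_count(lengths),
               vapply(lengths, window_count_brute, integer(1),
                      window = 1000, step = 500))
})

test_that("novelty calls require ANI >= 0.95 with AF >= 0.30 to be known", {
  matches <- data.frame(
    species_id = c("s1", "s2", "s3", "s3"),
    catalog = c("GTDB", "GTDB", "GEM", "SMAG"),
    ani = c(0.96, 0.96, 0.99, 0.94),
    af = c(0.50, 0.20, 0.80, 0.90))
  res <- classify_novel(c("s1", "s2", "s3", "s4"), matches)
  expect_false(res$novel_GTDB[1])          # qualifying match
  expect_true(res$novel_GTDB[2])           # AF below cutoff
  expect_false(res$novel_GEM[3])
  expect_true(res$novel_SMAG[3])           # ANI below cutoff
  expect_true(all(unlist(res[4, grep("^novel_", names(res))])))  # no match
  expect_equal(res$unique_to_catalog, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(classify_novel("s1", transform(matches, catalog = "IMG")),
               "unknown reference catalog")
})

test_that("exclusivity summary counts single-label species correctly", {
  mags <- data.frame(
    mag_id = paste0("m", 1:7),
    species_id = c("a", "a", "b", "b", "c", "d", "d"),
    region = c("Tibet", "Tibet", "Tibet", "Qilian", "Tibet", "Qilian", "Qilian"),
    ecosystem = c("River", "River", "Wetland", "Wetland", "River",
                  "Saline Lake", "Wetland"),
    site_id = c("x", "x", "y", "z", "x", "w", "w"))
  res <- exclusivity_summary(mags)
  expect_equal(res$n_species, 4)
  expect_equal(res$n_nonsingleton, 3)
  cnt <- res$counts
  expect_equal(cnt$n_exclusive[cnt$label == "region"], 3)  # a, c, d
  expect_equal(cnt$pct_exclusive[cnt$label == "region"], 75)
  expect_equal(cnt$n_exclusive_nonsingleton[cnt$label == "region"], 2)
  expect_equal(cnt$n_exclusive[cnt$label == "ecosystem"], 3)  # a, b, c
  expect_equal(cnt$n_exclusive[cnt$label == "site"], 3)       # a, c, d
  # every species spread across regions -> 0% exclusive
  spread <- data.frame(mag_id = paste0("m", 1:4),
                       species_id = c("a", "a", "b", "b"),
                       region = c("Tibet", "Qilian", "Tibet", "Qilian"),
                       ecosystem = "River", site_id = "x")
  expect_equal(exclusivity_summary(spread)$counts$pct_exclusive[1], 0)
  expect_error(exclusivity_summary(mags[0, ]), "empty")
})

test_that("rarefaction hits exact endpoints and closed forms", {
  genes <- setNames(c(rep("c1", 30), rep("c2", 50), rep("c3", 20)),
                    paste0("g", 1:100))
  rc <- rarefaction_curve(genes, reps = 50, seed = 5)
  expect_equal(rc$mean_clusters[rc$fraction == 1], 3)   # full set
  # nondecreasing within Monte-Carlo tolerance
  expect_true(all(diff(rc$mean_clusters) >= -0.25))
  one <- rarefaction_curve(setNames(rep("c1", 40), paste0("g", 1:40)),
                           seed = 5)
  expect_true(all(one$mean_clusters[one$n_genes > 0] == 1))
  # singletons: distinct clusters = genes drawn, exactly
  singles <- setNames(paste0("c", 1:60), paste0("g", 1:60))
  rs <- rarefaction_curve(singles, seed = 9)
  expect_equal(rs$mean_clusters, floor(rs$fraction * 60 + 1e-9))
  expect_error(rarefaction_curve(character(0)), "empty")
})

test_that("contig-removal bookkeeping reports half-up percentages", {
  expect_equal(removal_bookkeeping(7183800, 73230)$pct, 1.02)
  expect_equal(removal_bookkeeping(1000, 0)$pct, 0)
  expect_equal(removal_bookkeeping(100, 100)$pct, 100)
  expect_error(removal_bookkeeping(10, 11), "exceeds")
})
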