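test_that("sliding windows follow the fixed 30/15 grid", {
  w60 <- sliding_windows(c(c1 = strrep("ACGT", 15)))  # L = 60
  expect_equal(w60$start, c(0, 15, 30))
  expect_equal(nchar(w60$sequence), rep(30, 3))
  expect_equal(nrow(sliding_windows(c(c1 = strrep("A", 30)))), 1)
  expect_equal(nrow(sliding_windows(c(c1 = strrep("A", 29)))), 0)
  # N-containing windows are dropped and counted
  s <- paste0(strrep("A", 14), "N", strrep("C", 45))
  wn <- sliding_windows(c(c1 = s))
  expect_equal(attr(wn, "n_dropped_n"), 1)
  expect_equal(wn$start, c(15, 30))
  expect_error(sliding_windows(character(0)), "empty")
  expect_error(sliding_windows(c(c1 = "ACGU")), "A/C/G/T/N")
  # formula vs brute enumeration across all lengths to 10 kb
  lens <- 0:10000
  counts <- ifelse(lens < 30, 0L, floor((lens - 30) / 15) + 1L)
  expect_equal(counts, vapply(lens, window_count_brute, integer(1)))
})

test_that("the naive oracle agrees with exhaustive string comparison", {
  set.seed(19)
  genome <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  cand <- sliding_windows(c(src = genome))[c(1, 40, 90), ]
  hits <- naive_match_oracle(cand, c(tgt = genome), max_mismatches = 3)
  for (i in seq_len(nrow(cand))) {
    fw <- brute_scan(cand$sequence[i], genome, 3)
    rv <- brute_scan(revcomp_chr(cand$sequence[i]), genome, 3)
    got <- hits[hits$candidate_id == cand$candidate_id[i], ]
    expect_equal(sort(got$evalue), sort(c(fw, rv)))
  }
  # exact substring: identity 100, evalue 0
  exact <- hits[hits$evalue == 0 & hits$strand == "+", ]
  expect_true(all(exact$identity == 100))
  expect_true(all(hits$coverage == 100))
  # 3 mismatches in 30 -> identity exactly 90: flip 3 bases to their
  # complements, which guarantees each differs from the original
  mm3_chars <- strsplit(cand$sequence[1], "")[[1]]
  for (pos in c(1, 5, 9)) {
    mm3_chars[pos] <- chartr("ACGT", "TGCA", mm3_chars[pos])
  }
  cand3 <- data.frame(candidate_id = "mm3",
                      sequence = paste(mm3_chars, collapse = ""))
  h3 <- naive_match_oracle(cand3, c(tgt = genome), max_mismatches = 3)
  expect_true(any(h3$identity == 90))
  # reverse-complement-only occurrence is reported with strand "-"
  probe <- "ACGTACGTACGGTTACCGGATCAGGCATTA"
  rc_only <- paste0(strrep("T", 50), revcomp_chr(probe), strrep("G", 50))
  hr <- naive_match_oracle(data.frame(candidate_id = "p", sequence = probe),
                           c(tgt = rc_only), max_mismatches = 0)
  expect_equal(hr$strand, "-")
  expect_equal(hr$identity, 100)
})

test_that("specificity filter reads the three criteria conjunctively", {
  cand <- data.frame(candidate_id = c("p1", "p2", "p3"),
                     contig_id = "c", start = c(0, 45, 90), length = 30)
  hit <- function(id, e, cov, idy, taxon = "other") {
    data.frame(candidate_id = id, taxon = taxon, evalue = e,
               coverage = cov, identity = idy)
  }
  expect_equal(specificity_filter(cand, hit("p1", 10, 70, 95))$candidate_id,
               c("p2", "p3"))
  expect_equal(nrow(specificity_filter(cand, hit("p1", 10, 70, 85))), 3)
  expect_equal(nrow(specificity_filter(cand, hit("p1", 25, 70, 95))), 3)
  expect_equal(nrow(specificity_filter(cand, hit("p1", 10, 50, 95))), 3)
  expect_equal(nrow(specificity_filter(cand, hit("p1", 0, 100, 100,
                                                 taxon = "self"),
                                       self_taxon = "self")), 3)
  empty <- hit("p1", 1, 100, 100)[0, ]
  expect_equal(nrow(specificity_filter(cand, empty)), 3)
  expect_error(specificity_filter(cand, hit("zz", 1, 100, 100)),
               "unknown candidate")
  # monotone: adding hits never enlarges the retained set
  h1 <- hit("p1", 10, 70, 95)
  h2 <- rbind(h1, hit("p2", 10, 80, 99))
  expect_true(all(specificity_filter(cand, h2)$candidate_id %in%
                    specificity_filter(cand, h1)$candidate_id))
})

test_that("cross-genus screen removes copies and keeps planted uniques", {
  for (s in c(1, 6)) {
    sim <- gen_probe_genomes(sim_config(seed = s))
    cand <- sliding_windows(sim$target)
    kept <- cross_set_uniqueness(cand, sim$offtargets, self_genus = "target")
    tr <- sim$truth$planted
    ukeys <- sprintf("%s:%d", tr$contig[tr$kind == "unique"],
                     tr$start[tr$kind == "unique"])
    skeys <- sprintf("%s:%d", tr$contig[tr$kind == "shared"],
                     tr$start[tr$kind == "shared"])
    expect_true(all(ukeys %in% kept$candidate_id))
    expect_false(any(skeys %in% kept$candidate_id))
  }
  # empty reference collection: identity
  sim <- gen_probe_genomes(sim_config(seed = 1))
  cand <- sliding_windows(sim$target)
  expect_identical(cross_set_uniqueness(cand,
                                        Biostrings::DNAStringSet(),
                                        "target"), cand)
  unlabeled <- c("ACGT")
  expect_error(cross_set_uniqueness(cand, unlabeled, "target"), "labeled")
})

test_that("probe-set selection enforces distinct loci and the size cap", {
  cand <- data.frame(candidate_id = paste0("p", 1:25), contig_id = "c",
                     start = seq(0, by = 45, length.out = 25), length = 30)
  sel <- select_probe_set(cand, k = 10)
  expect_equal(nrow(sel), 10)
  expect_warning(s4 <- select_probe_set(cand[1:4, ], k = 10), "only 4")
  expect_equal(nrow(s4), 4)
  over <- data.frame(candidate_id = c("a", "b"), contig_id = "c",
                     start = c(0, 15), length = 30)
  expect_warning(s1 <- select_probe_set(over, k = 2))
  expect_equal(nrow(s1), 1)
  # near-miss ranking puts cleaner probes first
  ranked <- select_probe_set(cand[1:3, ], k = 2,
                             near_miss = c(p1 = 5, p2 = 0, p3 = 1))
  expect_equal(ranked$candidate_id, c("p2", "p3"))
})
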