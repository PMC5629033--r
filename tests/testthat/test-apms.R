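test_that("NSAF normalization matches its defining formula", {
  # single detected protein carries the whole purification
  one <- counts_tbl(10, 0, 2)
  expect_equal(compute_nsaf(one, meta_tbl("P001"))$nsaf, 1.0)

  # equal SpC/L gives equal shares
  two <- counts_tbl(c(10, 20), c(0, 0), c(2, 2))
  m2 <- meta_tbl(two$accession, length_aa = c(100, 200))
  expect_equal(compute_nsaf(two, m2)$nsaf, c(0.5, 0.5))

  # random table equals the brute-force oracle to 1e-12 and sums to 1
  withr::with_seed(101, {
    counts <- counts_tbl(rpois(50, 20), rpois(50, 5), rpois(50, 3) + 1)
    meta <- meta_tbl(counts$accession, length_aa = sample(100:3000, 50))
  })
  got <- compute_nsaf(counts, meta)
  oracle <- nsaf_oracle(counts, meta)
  expect_equal(setNames(got$nsaf, got$accession), oracle, tolerance = 1e-12)
  expect_equal(sum(got$nsaf), 1, tolerance = 1e-12)

  # missing length for a detected protein names the accession
  expect_error(compute_nsaf(two, m2[1, ]), "P002")
})

test_that("NSAF is invariant to a common rescaling of all lengths", {
  withr::with_seed(7, {
    counts <- counts_tbl(rpois(30, 15), rpois(30, 4), rep(2, 30))
    meta <- meta_tbl(counts$accession, length_aa = sample(100:2000, 30))
  })
  meta2 <- meta
  meta2$length_aa <- meta2$length_aa * 3L
  expect_equal(compute_nsaf(counts, meta)$nsaf,
               compute_nsaf(counts, meta2)$nsaf, tolerance = 1e-12)
})

test_that("candidate filter applies inclusive spectral-count and fold bounds", {
  tab <- counts_tbl(c(10, 9, 40, 39, 12, 10),
                    c(0, 0, 10, 10, 3, 0),
                    c(2, 2, 2, 2, 2, 1))
  kept <- filter_candidates(tab)
  expect_true("P001" %in% kept)   # bait-unique at exactly 10 SpC
  expect_false("P002" %in% kept)  # 9 SpC fails the >= 10 floor
  expect_true("P003" %in% kept)   # exactly 4-fold enrichment (inclusive)
  expect_false("P004" %in% kept)  # 3.9-fold fails
  expect_true("P005" %in% kept)   # 4-fold, 12 >= 10
  expect_false("P006" %in% kept)  # one unique peptide fails
})

test_that("candidate filter equals row-wise predicate evaluation exhaustively", {
  # boundary grid: bait x control crossing all three sub-threshold regions
  grid <- expand.grid(bait = c(0, 9, 10, 11, 39, 40, 41),
                      control = c(0, 1, 2, 3, 10, 11),
                      uniq = c(1, 2, 3))
  tab <- counts_tbl(grid$bait, grid$control, grid$uniq,
                    acc = sprintf("G%03d", seq_len(nrow(grid))))
  expect_identical(filter_candidates(tab), filter_oracle(tab))

  # random tables too
  for (s in 1:5) {
    withr::with_seed(s, {
      tab <- counts_tbl(rpois(80, 12), rpois(80, 4), rpois(80, 2))
    })
    expect_identical(filter_candidates(tab), filter_oracle(tab))
  }
})

test_that("filter thresholds are monotone and localization is a pure conjunction", {
  sim <- simulate_apms(sim_config(seed = 13))
  base <- filter_candidates(sim$counts)
  stricter_spc <- filter_candidates(sim$counts, apms_config(min_spectra = 15))
  stricter_fold <- filter_candidates(sim$counts, apms_config(min_fold = 8))
  expect_true(all(stricter_spc %in% base))
  expect_true(all(stricter_fold %in% base))

  # count-then-localization equals localization-then-count
  all_loc <- apms_config(allowed_localizations = c("nuclear", "unknown"))
  a <- filter_localization(filter_candidates(sim$counts), sim$meta, all_loc)
  pre <- filter_localization(sim$counts$accession, sim$meta, all_loc)
  b <- filter_candidates(sim$counts[sim$counts$accession %in% pre, ], all_loc)
  expect_identical(a, b)
})

test_that("localization filter keeps the allowed classes only", {
  meta <- meta_tbl(c("P1", "P2", "P3"),
                   localization = c("nuclear", "other", "unknown"))
  expect_identical(filter_localization(c("P1", "P2", "P3"), meta),
                   c("P1", "P3"))
  all3 <- apms_config(allowed_localizations = c("nuclear", "unknown", "other"))
  expect_identical(filter_localization(c("P1", "P2", "P3"), meta, all3),
                   c("P1", "P2", "P3"))
  expect_identical(filter_localization(character(0), meta), character(0))
  expect_error(filter_localization("P9", meta), "P9")
})

test_that("enrichment-index ranking is monotone in 1/abundance with stable ties", {
  nsaf <- tibble::tibble(accession = c("A", "B"), nsaf = c(0.1, 0.1))
  meta <- meta_tbl(c("A", "B"), abundance_ppm = c(10, 100))
  ranked <- rank_by_enrichment_index(c("A", "B"), nsaf, meta)
  expect_identical(ranked$accession, c("A", "B"))
  expect_equal(ranked$enrichment_index, c(0.01, 0.001))
  expect_identical(ranked$rank, 1:2)

  # top_k larger than the candidate set returns everything
  expect_equal(nrow(rank_by_enrichment_index(
    c("A", "B"), nsaf, meta, apms_config(top_k = 50))), 2)

  # equal index ties break by accession ascending
  meta_tie <- meta_tbl(c("B", "A"), abundance_ppm = 10)
  tie <- rank_by_enrichment_index(c("B", "A"), nsaf, meta_tie)
  expect_identical(tie$accession, c("A", "B"))
})

test_that("missing whole-cell abundance follows the configured policy", {
  nsaf <- tibble::tibble(accession = c("A", "B", "C"), nsaf = c(0.5, 0.3, 0.2))
  meta <- meta_tbl(c("A", "B", "C"), abundance_ppm = c(NA, 4, 0))
  ranked <- rank_by_enrichment_index(c("A", "B", "C"), nsaf, meta)
  # NA and 0 imputed with the dataset minimum positive abundance (4), flagged
  expect_true(all(ranked$abundance_imputed[ranked$accession %in% c("A", "C")]))
  expect_equal(ranked$abundance_ppm, rep(4, 3))

  excl <- rank_by_enrichment_index(
    c("A", "B", "C"), nsaf, meta, apms_config(missing_abundance_policy = "exclude"))
  expect_identical(excl$accession, "B")

  meta_none <- meta_tbl(c("A", "B", "C"), abundance_ppm = c(NA, NA, 0))
  expect_error(rank_by_enrichment_index(c("A", "B", "C"), nsaf, meta_none),
               "impute")
})

test_that("top-50 false discoveries shrink as planted enrichment grows", {
  fdp_at <- function(factor) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_apms(sim_config(enrichment_factor = factor, seed = s))
      ranked <- score_apms(sim$counts, sim$meta)
      if (nrow(ranked) == 0) return(0)
      mean(!ranked$accession %in% sim$truth$interactors)
    }, numeric(1)))
  }
  fdp <- vapply(c(4, 8, 16), fdp_at, numeric(1))
  expect_lte(fdp[3], fdp[1])
  expect_lte(fdp[2], fdp[1] + 0.02)
})
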