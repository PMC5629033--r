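chans <- tmt_channels()

test_that("total-sum normalization equalizes channel totals and preserves ratios", {
  ab <- tibble::tibble(accession = c("A", "B"),
                       ctl_1 = c(60, 40), ctl_2 = c(150, 50),
                       mut_1 = c(80, 20), mut_2 = c(90, 110))
  norm <- normalize_channels(ab, chans)
  totals <- vapply(chans$channel, function(ch) sum(norm[[ch]]), numeric(1))
  expect_equal(unname(totals), rep(150, 4))  # mean of (100, 200, 100, 200)

  # "none" is the identity
  expect_identical(normalize_channels(ab, chans, "none"), ab)

  # within-channel ratios between proteins unchanged (random matrices)
  for (s in 1:5) {
    withr::with_seed(s, {
      ab2 <- tibble::tibble(accession = sprintf("P%02d", 1:20),
                            ctl_1 = runif(20, 1, 100), ctl_2 = runif(20, 1, 100),
                            mut_1 = runif(20, 1, 100), mut_2 = runif(20, 1, 100))
    })
    n2 <- normalize_channels(ab2, chans)
    for (ch in chans$channel) {
      expect_equal(n2[[ch]][1] / n2[[ch]][2], ab2[[ch]][1] / ab2[[ch]][2],
                   tolerance = 1e-12)
    }
    # idempotence: normalizing twice equals normalizing once
    expect_equal(normalize_channels(n2, chans), n2, tolerance = 1e-12)
  }

  ab_zero <- ab
  ab_zero$ctl_1 <- 0
  expect_error(normalize_channels(ab_zero, chans), "ctl_1")
})

test_that("replicate concordance is 1 for an exact scalar multiple", {
  withr::with_seed(2, x <- runif(100, 1, 1000))
  ab <- tibble::tibble(accession = sprintf("P%03d", 1:100),
                       ctl_1 = x, ctl_2 = 2.5 * x,
                       mut_1 = x, mut_2 = x)
  expect_equal(replicate_concordance(ab, chans, "control"), 1.0,
               tolerance = 1e-12)
  expect_error(replicate_concordance(ab[1:2, ], chans, "control"), "3")
})

test_that("simulated duplicates show the high concordance the noise model implies", {
  sim <- simulate_tmt(sim_config(n_proteins = 3000, seed = 21))
  expect_gt(replicate_concordance(sim$abundance, sim$channels, "control"), 0.95)
  expect_gt(replicate_concordance(sim$abundance, sim$channels, "mutant"), 0.95)
})

test_that("ratio-distribution fit recovers center, spread and coverage", {
  # 10,000 ratios from a centered log2-normal with the 90%/1.3-fold sigma
  sigma <- log2(1.3) / qnorm(0.95)
  withr::with_seed(31, r <- rnorm(10000, 0, sigma))
  ab <- tibble::tibble(accession = sprintf("P%05d", seq_along(r)),
                       ctl_1 = 2^(r / 2), ctl_2 = 2^(-r / 2),
                       mut_1 = 1, mut_2 = 1)
  fit <- fit_ratio_distribution(ab, chans, "control")
  expect_false(fit$fallback)
  expect_equal(fit$empirical_fraction_within, 0.90, tolerance = 0.012)
  expect_equal(fit$sigma_log2, sigma, tolerance = 0.05)
  expect_equal(fit$mu_log2, 0, tolerance = 0.02)
  expect_equal(fit$central90_halfwidth_log2, qnorm(0.95) * fit$sigma_log2)

  # fitted sigma within 5% of the generating sigma across seeds
  rel_err <- vapply(1:20, function(s) {
    sim <- simulate_tmt(sim_config(n_proteins = 3000, seed = s))
    f <- fit_ratio_distribution(sim$abundance, sim$channels, "control")
    abs(f$sigma_log2 - sigma) / sigma
  }, numeric(1))
  expect_lt(max(rel_err), 0.05)
})

test_that("degenerate ratio input falls back to the robust estimate", {
  ab <- tibble::tibble(accession = sprintf("P%02d", 1:10),
                       ctl_1 = 5, ctl_2 = 5, mut_1 = 5, mut_2 = 5)
  fit <- fit_ratio_distribution(ab, chans, "control")
  expect_true(fit$fallback)
  expect_equal(fit$sigma_log2, 0)
})

test_that("threshold derivation inverts the coverage calibration", {
  sigma <- log2(1.3) / qnorm(0.95)
  expect_equal(derive_threshold(sigma, 0.90), 1.30, tolerance = 5e-4)
  # frozen z-quantile arithmetic: qnorm(0.75) = 0.6744898 from a standard
  # normal table, tau = 2^(0.6744898 * 0.23013)
  expect_equal(derive_threshold(0.23013, 0.50), 2^(0.6744898 * 0.23013),
               tolerance = 1e-6)
  expect_equal(derive_threshold(0.23013, 0.50), 1.1135, tolerance = 1e-4)
  expect_equal(derive_threshold(0, 0.90), 1)
  expect_error(derive_threshold(sigma, 1.2), "coverage")

  # accepts a fitted object directly
  sim <- simulate_tmt(sim_config(n_proteins = 3000, seed = 4))
  fit <- fit_ratio_distribution(sim$abundance, sim$channels, "control")
  expect_equal(derive_threshold(fit, 0.90), 1.30, tolerance = 0.05)
})

test_that("differential calls apply the concordant two-replicate rule inclusively", {
  ab <- tmt_from_ratios(r1 = c(1.0, 1.3, 1.5, 0.70, 1.3),
                        r2 = c(1.0, 1.5, 1.2, 0.76, 1.3))
  calls <- call_differential(ab, chans, normalization = "none")
  expect_identical(calls$direction, c("none", "up", "none", "down", "up"))
  s <- glance(calls)
  expect_equal(s$n_up, 2)
  expect_equal(s$n_down, 1)
  expect_equal(s$n_total, 3)

  # a zero abundance makes the protein not evaluable and uncounted
  ab$mut_1[1] <- 0
  calls0 <- call_differential(ab, chans, normalization = "none")
  expect_false(calls0$evaluable[1])
  expect_true(is.na(calls0$direction[1]))
  expect_equal(glance(calls0)$n_evaluated, 4)
})

test_that("direction labels are antisymmetric under group swap", {
  sim <- simulate_tmt(sim_config(n_proteins = 500, seed = 8))
  swapped <- sim$channels
  swapped$group <- ifelse(swapped$group == "control", "mutant", "control")
  a <- call_differential(sim$abundance, sim$channels)
  b <- call_differential(sim$abundance, swapped)
  expect_identical(a$direction == "up", b$direction == "down")
  expect_identical(a$direction == "down", b$direction == "up")
})

test_that("raising the fold threshold never adds calls", {
  sim <- simulate_tmt(sim_config(n_proteins = 1000, seed = 15))
  taus <- c(1.2, 1.3, 1.5, 2.0)
  counts <- lapply(taus, function(t) {
    glance(call_differential(sim$abundance, sim$channels, fold_threshold = t))
  })
  for (i in seq_along(taus)[-1]) {
    expect_lte(counts[[i]]$n_up, counts[[i - 1]]$n_up)
    expect_lte(counts[[i]]$n_down, counts[[i - 1]]$n_down)
  }
})

test_that("calls are invariant to repeated total-sum normalization", {
  sim <- simulate_tmt(sim_config(n_proteins = 400, seed = 23))
  once <- call_differential(sim$abundance, sim$channels)
  pre <- normalize_channels(sim$abundance, sim$channels)
  twice <- call_differential(pre, sim$channels)
  expect_identical(once$direction, twice$direction)
  expect_equal(once$ratio_rep1, twice$ratio_rep1, tolerance = 1e-12)
})

test_that("averaged and cross pairings behave as stricter/looser variants", {
  ab <- tmt_from_ratios(r1 = c(1.4, 1.35), r2 = c(1.25, 1.35))
  # averaged variant classifies on the mean-abundance ratio
  avg <- call_differential(ab, chans, normalization = "none",
                           pairing = "average")
  expect_identical(avg$direction, c("up", "up"))
  # cross pairing requires all four cross-ratios to clear the threshold
  crs <- call_differential(ab, chans, normalization = "none",
                           pairing = "cross")
  expect_identical(crs$direction, c("none", "up"))
})
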