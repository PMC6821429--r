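# Differential APA statistics: PUI indices, chi-squared tests, direction
# calls, binomial and rank tests, intronic usage, per-cell summaries.

test_that("proximal PUI matches hand values and the closed-form identity", {
  expect_equal(proximal_pui(c(3, 3)), 0)
  expect_equal(proximal_pui(c(7, 1)), 1) # log2(8 / sqrt(8 * 2))
  expect_equal(proximal_pui(c(0, 0, 0)), 0)
  expect_error(proximal_pui(5), "two peaks")

  withr::with_seed(1, {
    for (i in 1:20) {
      counts <- sample(0:500, sample(2:4, 1), replace = TRUE)
      expect_equal(proximal_pui(counts), oracle_proximal_pui(counts),
        tolerance = 1e-12
      )
    }
  })
  # two-peak identity: PUI = 0.5 * log2((C1+1)/(C2+1))
  for (c1 in c(0, 3, 10, 250)) {
    for (c2 in c(0, 7, 99)) {
      expect_equal(
        proximal_pui(c(c1, c2)),
        0.5 * log2((c1 + 1) / (c2 + 1)),
        tolerance = 1e-12
      )
    }
  }
  # strictly increasing in the proximal count
  vals <- vapply(0:50, function(c1) proximal_pui(c(c1, 20, 5)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("intronic PUI matches hand values", {
  expect_equal(intronic_pui(3, 7), -1)
  expect_equal(intronic_pui(5, 5), 0)
  expect_equal(intronic_pui(0, 0), 0)
  expect_equal(intronic_pui(c(1, 3), c(3, 1)), c(-1, 1))
  expect_error(intronic_pui(-1, 0))
})

test_that("chi-squared and BH agree with from-scratch oracles", {
  withr::with_seed(3, {
    for (i in 1:50) {
      m <- matrix(rpois(6, 40) + 1, nrow = 2)
      cnt <- make_counts(m, clusters = c("c1", "c2", "c3"))
      res <- tidy(test_differential_usage(cnt))
      o <- oracle_chisq(m)
      expect_equal(res$chi2, o$statistic, tolerance = 1e-9)
      expect_equal(res$p, o$p, tolerance = 1e-9)
    }
    # BH across many tested UTRs matches the step-up oracle
    cnts <- purrr::map_dfr(1:80, function(u) {
      make_counts(matrix(rpois(4, 60) + 1, nrow = 2),
        region_id = sprintf("g%02d:1", u), gene_id = sprintf("g%02d", u)
      )
    })
    res <- tidy(test_differential_usage(cnts))
    expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)
  })
})

test_that("degenerate tables are identified, not tested", {
  flat <- make_counts(matrix(c(50L, 50L, 50L, 50L), nrow = 2))
  res <- tidy(test_differential_usage(flat))
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  # one cluster empty for this UTR -> dropped -> untestable
  onecol <- make_counts(matrix(c(50L, 50L, 0L, 0L), nrow = 2))
  res <- tidy(test_differential_usage(onecol))
  expect_false(res$testable)
  expect_true(is.na(res$p))
})

test_that("direction calls follow the proximal PUI comparison", {
  expect_equal(classify_direction(c(80, 20), c(20, 80)), "shortened_in_A")
  expect_equal(classify_direction(c(20, 80), c(80, 20)), "lengthened_in_A")
  expect_true(is.na(classify_direction(c(50, 50), c(50, 50))))
  expect_error(classify_direction(c(1, 2, 3), c(1, 2, 3)), "two-peak")

  cnt <- make_counts(matrix(c(80L, 20L, 20L, 80L), nrow = 2))
  res <- tidy(test_differential_usage(cnt, pair = c("c1", "c2")))
  expect_equal(res$direction, "shortened_in_c1")
})

test_that("binomial direction test matches closed forms", {
  expect_equal(binomial_direction_test(10, 0)$p, 2^-10, tolerance = 1e-12)
  expect_equal(binomial_direction_test(5, 5)$p, oracle_binom_upper(5, 10),
    tolerance = 1e-12
  )
  expect_equal(binomial_direction_test(1, 0)$p, 0.5)
  expect_equal(binomial_direction_test(0, 7)$dominant, "lengthened")
  expect_error(binomial_direction_test(-1, 3))
})

test_that("rank tests pick Wilcoxon or Kruskal-Wallis by group count", {
  same <- list(a = 1:20 / 10, b = 1:20 / 10)
  res <- compare_pui_distributions(same)
  expect_equal(res$method, "wilcoxon")
  expect_gt(res$p, 0.9)

  withr::with_seed(8, {
    shifted <- list(a = rnorm(200), b = rnorm(200, 2))
  })
  expect_lt(compare_pui_distributions(shifted)$p, 1e-6)
  # pre-registered direction: one-tailed in the wrong direction is ~1
  expect_gt(compare_pui_distributions(shifted, alternative = "greater")$p, 0.99)
  expect_lt(compare_pui_distributions(shifted, alternative = "less")$p, 1e-6)

  three <- list(a = 1:20, b = 1:20, c = 1:20)
  res3 <- compare_pui_distributions(three)
  expect_equal(res3$method, "kruskal-wallis")
  expect_gt(res3$p, 0.99)
  expect_error(compare_pui_distributions(list(a = 1, b = numeric(0))), "at least one")
})

test_that("per-peak tests localise the shifting peak", {
  withr::with_seed(17, {
    # three peaks; only peak 1's share changes between clusters
    c1 <- as.integer(rmultinom(1, 500, c(0.5, 0.25, 0.25)))
    c2 <- as.integer(rmultinom(1, 500, c(0.2, 0.4, 0.4)))
  })
  cnt <- make_counts(cbind(c1, c2), clusters = c("c1", "c2"))
  res <- per_peak_tests(cnt)
  expect_lt(res$q[1], 0.05)
  # proportional counts: all p near 1... peaks 2 and 3 keep their 1:1 ratio
  # within the remainder, so they may drift; only exact proportionality is flat
  prop <- make_counts(matrix(c(100L, 200L, 300L, 50L, 100L, 150L), nrow = 3),
    clusters = c("c1", "c2")
  )
  res_prop <- per_peak_tests(prop)
  expect_true(all(res_prop$p > 0.99))
  # two-peak case collapses to the global test
  two <- make_counts(matrix(c(80L, 20L, 40L, 60L), nrow = 2))
  expect_equal(
    per_peak_tests(two)$p[1],
    tidy(test_differential_usage(two))$p,
    tolerance = 1e-12
  )
})

test_that("intronic usage testing is strand-aware about 'downstream'", {
  intron <- make_counts(matrix(c(10L, 10L), ncol = 2),
    region_id = "g1:I1",
    edges = 500L
  )
  utr <- make_counts(matrix(c(100L, 50L, 100L, 50L), nrow = 2), edges = c(1000L, 1400L))
  res <- tidy(test_intronic_usage(intron, utr))
  expect_equal(res$cu_c1, 150)
  expect_equal(res$p, 1, tolerance = 1e-9) # Ci (10,10) vs CU (150,150)

  shifted <- make_counts(matrix(c(10L, 100L), ncol = 2),
    region_id = "g1:I1",
    edges = 500L
  )
  res2 <- tidy(test_intronic_usage(shifted, utr, pair = c("c1", "c2")))
  expect_true(res2$significant)
  expect_equal(res2$direction, "down_in_c1")
  expect_equal(res2$ipui_c1, log2(11 / 151))

  # minus strand: only UTR peaks with lower coordinates are downstream
  intron_m <- dplyr::mutate(intron, strand = "-", three_prime_edge = 500L)
  utr_m <- dplyr::mutate(utr, strand = "-", three_prime_edge = c(390L, 1400L))
  res_m <- tidy(suppressMessages(test_intronic_usage(intron_m, utr_m)))
  expect_equal(res_m$cu_c1, 100) # only the 390-edge peak counts
  # no downstream counts at all -> untestable
  utr_up <- dplyr::mutate(utr_m, three_prime_edge = c(900L, 1400L))
  res_none <- tidy(suppressMessages(test_intronic_usage(intron_m, utr_up)))
  expect_false(res_none$testable)
})

test_that("per-cell mean PUI averages qualifying multi-peak UTRs", {
  # two 2-peak UTRs; cell X has one read at each proximal peak -> mean 0.5
  cnt <- dplyr::bind_rows(
    make_counts(matrix(c(1L, 0L, 0L, 0L), nrow = 2), clusters = c("X", "Y")),
    make_counts(matrix(c(1L, 0L, 0L, 0L), nrow = 2),
      region_id = "g2:1",
      gene_id = "g2", clusters = c("X", "Y")
    )
  )
  res <- per_cell_mean_pui(cnt)
  expect_equal(res$mean_pui[res$barcode == "X"], 0.5)
  expect_equal(res$n_utrs[res$barcode == "X"], 2)
  expect_true(is.na(res$mean_pui[res$barcode == "Y"]))
})

test_that("null count tables keep the false-discovery rate in check", {
  withr::with_seed(29, {
    cnts <- purrr::map_dfr(1:200, function(u) {
      make_counts(
        cbind(
          rmultinom(1, 500, c(0.4, 0.6)),
          rmultinom(1, 500, c(0.4, 0.6))
        ),
        region_id = sprintf("g%03d:1", u), gene_id = sprintf("g%03d", u)
      )
    })
  })
  res <- tidy(test_differential_usage(cnts))
  expect_lte(mean(res$p < 0.05), 0.1) # ~5% expected
  expect_lte(sum(res$significant), 2) # BH leaves essentially none
})
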