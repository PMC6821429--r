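# Peak calling, region assignment, mixture splitting, edge benchmarking and
# PAS scanning.

test_that("pool_reads_by_cluster partitions reads and tallies drops", {
  reads <- make_reads(c(100, 100, 200), c(199, 199, 299),
    barcode = c("A", "A", "B")
  )
  asg <- tibble::tibble(barcode = c("A", "B"), cluster = c("c1", "c2"))
  pooled <- suppressMessages(pool_reads_by_cluster(reads, asg))
  expect_equal(sum(pooled$cluster == "c1"), 2)
  expect_equal(sum(pooled$cluster == "c2"), 1)
  expect_equal(attr(pooled, "dropped"), 0)

  reads$barcode[3] <- "C" # not in the assignment
  expect_message(
    pooled <- pool_reads_by_cluster(reads, asg),
    "1 read\\(s\\).*dropped"
  )
  expect_equal(attr(pooled, "dropped"), 1)
  expect_equal(nrow(pooled), 2)

  none <- tibble::tibble(barcode = "Z", cluster = "c1")
  expect_error(pool_reads_by_cluster(reads, none), "no read barcode")
})

test_that("call_peaks matches hand cases and the per-base coverage oracle", {
  # one pileup of identical reads
  r <- make_reads(rep(100, 10), rep(199, 10))
  pk <- call_peaks(r, min_reads = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end, pk$n_reads), c(100, 199, 10))
  expect_equal(pk$member_pos[[1]], rep(199L, 10))

  # disjoint pileups stay separate at max_gap = 0
  r <- make_reads(c(100, 500), c(199, 599))
  expect_equal(nrow(call_peaks(r, min_reads = 1)), 2)

  # staggered overlapping reads chain into one interval
  r <- make_reads(c(100, 150, 240), c(199, 249, 339))
  pk <- call_peaks(r, min_reads = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(100, 339))

  # property: random read sets agree with the per-base oracle, both strands
  withr::with_seed(42, {
    for (rep_i in 1:5) {
      n <- 60
      starts <- sample.int(5000, n, replace = TRUE)
      ends <- starts + sample(20:150, n, replace = TRUE)
      strand <- sample(c("+", "-"), 1)
      gap <- sample(0:30, 1)
      minr <- sample(1:4, 1)
      got <- call_peaks(make_reads(starts, ends, strand = strand),
        min_reads = minr, max_gap = gap
      )
      exp <- oracle_call_peaks(starts, ends, min_reads = minr, max_gap = gap)
      expect_equal(got[, c("start", "end", "n_reads")], exp, ignore_attr = TRUE)
    }
  })
})

test_that("min_reads discards weak intervals and empty input is fine", {
  r <- make_reads(c(100, 100, 100, 500), c(199, 199, 199, 599))
  pk <- call_peaks(r, min_reads = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 100)
  expect_equal(nrow(call_peaks(r[0, ], min_reads = 1)), 0)
})

test_that("proximal peak indexing follows transcript orientation", {
  utr_plus <- tibble::tibble(
    utr_id = "gp:1", gene_id = "gp", chrom = "chr1",
    start = 900, end = 1500, strand = "+"
  )
  utr_minus <- dplyr::mutate(utr_plus,
    utr_id = "gm:1", gene_id = "gm", strand = "-"
  )
  two_peaks <- function(strand) {
    dplyr::bind_rows(
      call_peaks(make_reads(rep(1000, 5), rep(1099, 5), strand = strand), min_reads = 1),
      call_peaks(make_reads(rep(1300, 5), rep(1399, 5), strand = strand), min_reads = 1)
    )
  }
  plus <- assign_peaks(two_peaks("+"), utr_plus)
  expect_equal(plus$peak_id[plus$start == 1000], "gp:1_1")
  expect_equal(plus$peak_id[plus$start == 1300], "gp:1_2")

  minus <- assign_peaks(two_peaks("-"), utr_minus)
  expect_equal(minus$peak_id[minus$start == 1300], "gm:1_1")
  expect_equal(minus$peak_id[minus$start == 1000], "gm:1_2")
})

test_that("assignment uses the larger overlap and keeps unassigned peaks", {
  regions <- tibble::tibble(
    utr_id = c("a:1", "b:1"), gene_id = c("a", "b"), chrom = "chr1",
    start = c(100, 260), end = c(250, 400), strand = "+"
  )
  # peak [200,350]: 51 bases in a:1, 91 in b:1 -> b:1
  pk <- call_peaks(make_reads(rep(200, 5), rep(350, 5)), min_reads = 1)
  asg <- assign_peaks(pk, regions)
  expect_equal(asg$region_id, "b:1")

  # no overlap -> unassigned but retained
  far <- call_peaks(make_reads(rep(5000, 5), rep(5100, 5)), min_reads = 1)
  asg <- assign_peaks(far, regions)
  expect_true(is.na(asg$region_id))
  expect_true(is.na(asg$peak_id))

  # strand mismatch does not assign
  rev <- call_peaks(make_reads(rep(200, 5), rep(350, 5), strand = "-"), min_reads = 1)
  expect_true(is.na(assign_peaks(rev, regions)$region_id))
})

test_that("mixture fitting splits clear bimodality and spares unimodal peaks", {
  withr::with_seed(7, {
    # unimodal: no split for any reasonable fit
    uni <- round(rnorm(200, 100, 15))
    fit <- fit_peak_mixture(uni)
    expect_false(should_split(fit))

    # clear bimodality: split with means recovered within +/- 5
    bi <- c(round(rnorm(100, 100, 10)), round(rnorm(100, 300, 10)))
    fit <- fit_peak_mixture(bi)
    expect_true(should_split(fit))
    expect_lt(abs(fit$mu1 - 100), 5)
    expect_lt(abs(fit$mu2 - 300), 5)
    expect_gt(fit$boundary, fit$mu1)
    expect_lt(fit$boundary, fit$mu2)

    # modes 60 nt apart fail the 75 nt distance rule
    near <- c(round(rnorm(100, 100, 10)), round(rnorm(100, 160, 10)))
    expect_false(should_split(fit_peak_mixture(near)))
  })
})

test_that("EM agrees with mclust on a synthetic mixture", {
  skip_if_not_installed("mclust")
  withr::with_seed(13, {
    x <- c(rnorm(150, 0, 12), rnorm(150, 250, 20))
  })
  fit <- fit_peak_mixture(x)
  # Mclust resolves mclustBIC in the caller's environment
  mclustBIC <- mclust::mclustBIC
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu_mc <- sort(mc$parameters$mean)
  expect_lt(abs(fit$mu1 - mu_mc[1]), 3)
  expect_lt(abs(fit$mu2 - mu_mc[2]), 3)
  expect_lt(abs(fit$loglik - mc$loglik), 1)
})

test_that("split peaks conserve members and re-derive edges and indices", {
  withr::with_seed(21, {
    pos <- sort(c(round(rnorm(60, 1100, 10)), round(rnorm(60, 1400, 10))))
  })
  reads <- make_reads(pos - 99, pos)
  pk <- call_peaks(reads, min_reads = 1, max_gap = 500)
  expect_equal(nrow(pk), 1)
  utr <- tibble::tibble(
    utr_id = "g1:1", gene_id = "g1", chrom = "chr1",
    start = 1000, end = 1500, strand = "+"
  )
  asg <- assign_peaks(pk, utr)
  sp <- split_bimodal_peaks(asg)
  expect_equal(nrow(sp), 2)
  expect_equal(attr(sp, "n_split"), 1)
  expect_setequal(unlist(sp$member_pos), pos)
  expect_equal(sum(sp$n_reads), length(pos))
  expect_equal(sp$peak_id, c("g1:1_1", "g1:1_2"))
  expect_equal(sp$three_prime_edge, sp$end) # plus strand
  # sub-peak intervals span exactly their members
  expect_equal(sp$start, vapply(sp$member_pos, min, numeric(1)))
  expect_equal(sp$end, vapply(sp$member_pos, max, numeric(1)))
  # small peaks are never split
  few <- dplyr::mutate(asg,
    member_pos = list(pos[1:10]),
    n_reads = 10L
  )
  expect_equal(nrow(split_bimodal_peaks(few)), 1)
})

test_that("edge distances are signed in transcript orientation", {
  pk <- tibble::tibble(
    chrom = "chr1", start = 900, end = 1000, strand = "+",
    three_prime_edge = 1000
  )
  sites <- tibble::tibble(
    chrom = "chr1", position = c(900, 1040), strand = "+"
  )
  expect_equal(peak_edge_distance(pk, sites)$ref_distance, 40)
  exact <- tibble::tibble(chrom = "chr1", position = 1000, strand = "+")
  expect_equal(peak_edge_distance(pk, exact)$ref_distance, 0)
  wrong_strand <- tibble::tibble(chrom = "chr1", position = 1000, strand = "-")
  expect_true(is.na(peak_edge_distance(pk, wrong_strand)$ref_distance))
  # minus strand: a reference downstream (lower coordinate) is positive
  pkm <- dplyr::mutate(pk, strand = "-", three_prime_edge = 900)
  down <- tibble::tibble(chrom = "chr1", position = 860, strand = "-")
  expect_equal(peak_edge_distance(pkm, down)$ref_distance, 40)
})

test_that("PAS scanning is strand-aware over the edge window", {
  genome <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("C", 1010), "AATAAA", strrep("C", 200))
  ))
  pk <- tibble::tibble(
    chrom = "chrA", start = 900, end = 1000, strand = "+",
    three_prime_edge = 1000
  )
  expect_true(scan_pas_motifs(pk, genome)$pas_hit) # hexamer at +11..+16
  allc <- Biostrings::DNAStringSet(c(chrA = strrep("C", 1300)))
  expect_false(scan_pas_motifs(pk, allc)$pas_hit)
  # on the minus strand the same genomic bases read TTTATT: no sense hit
  pkm <- dplyr::mutate(pk, strand = "-", three_prime_edge = 900)
  expect_false(scan_pas_motifs(pkm, genome)$pas_hit)
  # but a planted TTTATT upstream-of-minus-edge reads AATAAA in sense
  genome_m <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("C", 850), "TTTATT", strrep("C", 400))
  ))
  expect_true(scan_pas_motifs(pkm, genome_m)$pas_hit)
})

test_that("peak calling on the default simulation recovers true sites", {
  sim <- default_sim()
  pk <- default_sim_peaks()
  truth <- sim$reference$sites
  covered <- sim$read_truth |>
    dplyr::filter(!internal_priming) |>
    dplyr::count(gene_id, site_type, site_index) |>
    dplyr::filter(n >= 20)
  truth <- dplyr::inner_join(truth, covered,
    by = c("gene_id", "site_type", "site_index")
  )
  peaks <- dplyr::bind_rows(pk$utr_peaks, pk$intron_peaks)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(peaks$chrom == truth$chrom[i] & peaks$strand == truth$strand[i] &
      abs(peaks$three_prime_edge - truth$position[i]) <= 50)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
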