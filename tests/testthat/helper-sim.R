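# Shared simulation fixtures. The default experiment is expensive, so it is
# built once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

# The default study conditions: 60 two-site genes, two clusters with a
# 0.3/0.7 vs 0.7/0.3 proximal/distal usage shift, 100 cells per cluster at
# ~1000 reads per cell (~200k reads), 5% internal priming, planted PAS.
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    cfg <- sim_config(seed = 20260923)
    ref <- simulate_reference(cfg)
    rd <- simulate_reads(cfg, ref)
    .sim_cache$default <- c(list(config = cfg, reference = ref), rd)
  }
  .sim_cache$default
}

# Pipeline products on the default simulation, cached likewise.
default_sim_peaks <- function() {
  if (is.null(.sim_cache$peaks)) {
    sim <- default_sim()
    utr <- build_utr_regions(sim$reference$annotation)
    introns <- build_intron_regions(sim$reference$annotation, utr)
    raw <- call_peaks(sim$reads)
    utr_pk <- suppressMessages(assign_peaks(raw, utr))
    leftover <- dplyr::select(
      dplyr::filter(utr_pk, is.na(region_id)),
      -peak_id, -region_id, -gene_id, -peak_index
    )
    utr_pk <- suppressMessages(split_bimodal_peaks(
      dplyr::filter(utr_pk, !is.na(region_id))
    ))
    intron_pk <- suppressMessages(split_bimodal_peaks(
      dplyr::filter(assign_peaks(leftover, introns), !is.na(region_id))
    ))
    .sim_cache$peaks <- list(
      utr_regions = utr, intron_regions = introns, raw = raw,
      utr_peaks = utr_pk, intron_peaks = intron_pk
    )
  }
  .sim_cache$peaks
}

# small read tibble builder for hand fixtures
make_reads <- function(starts, ends, strand = "+", chrom = "chr1",
                       barcode = "BC1", cluster = NULL) {
  n <- length(starts)
  out <- tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    chrom = rep_len(chrom, n),
    start = as.integer(starts), end = as.integer(ends),
    strand = rep_len(strand, n),
    barcode = rep_len(barcode, n)
  )
  if (!is.null(cluster)) out$cluster <- rep_len(cluster, n)
  out
}

# count tibble builder: one UTR region with per-peak, per-cluster counts
make_counts <- function(mat, region_id = "g1:1", gene_id = "g1",
                        strand = "+", chrom = "chr1",
                        edges = NULL, clusters = NULL) {
  k <- nrow(mat)
  clusters <- clusters %||% paste0("c", seq_len(ncol(mat)))
  edges <- edges %||% (1000L + (seq_len(k) - 1L) * 400L)
  idx <- seq_len(k)
  out <- tibble::tibble(
    peak_id = paste0(region_id, "_", idx),
    region_id = region_id, gene_id = gene_id, peak_index = idx,
    chrom = chrom,
    start = as.integer(edges - 100L), end = as.integer(edges),
    strand = strand, three_prime_edge = as.integer(edges)
  )
  for (j in seq_along(clusters)) out[[clusters[j]]] <- as.integer(mat[, j])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
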