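#' Default pipeline parameters
#'
#' Thresholds of the published analysis: peaks need more than 10 summed CPM
#' (UTR) or at least 50 counts and 10 CPM (introns); internal-priming windows
#' are 10-140 nt downstream with an 8-A run for UTR peaks and 1-200 nt with a
#' 7-A run for intronic peaks; bimodal peaks split at 3 fitted SDs and at
#' least 75 nt mode separation; FDR level 0.05.
#'
#' @return Named list of parameter defaults.
#' @export
apa_defaults <- function() {
  list(
    barcode_tag = "CB",
    min_mapq = 255,
    min_reads = 5,
    max_gap = 0,
    min_split_reads = 20,
    split_min_distance = 75,
    split_sd_factor = 3,
    min_cpm_utr = 10,
    a_run_utr = 8,
    window_utr = c(10, 140),
    min_count_intron = 50,
    min_cpm_intron = 10,
    a_run_intron = 7,
    window_intron = c(1, 200),
    fdr = 0.05,
    pair = NULL,
    caller = "coverage",
    seed = 1
  )
}

#' Read a flat key-value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Comma-separated
#' values become vectors; numeric-looking values are converted.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "), call. = FALSE)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], "\\s*,\\s*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[`, character(1), 1))
}

#' Run the APA pipeline end to end
#'
#' Sequences all stages: region building, read pooling, peak calling,
#' UTR/intron assignment, bimodal splitting, counting, filtering,
#' differential-usage statistics, expression quantification and per-cell
#' summaries. Every intermediate is written under `out_dir` and a JSON
#' manifest records parameters, the seed and per-stage tallies.
#'
#' @param config Named list (or path to a key-value file, see
#'   [read_pipeline_config()]) with entries `bam` (SAM/BAM), `gtf`, `fasta`,
#'   `clusters` (TSV with barcode, cluster), optional `reference_bed`
#'   (single-base pA sites for benchmarking), `out_dir`, and any parameter
#'   from [apa_defaults()].
#' @param stop_after Last stage to execute, one of `"regions"`, `"peaks"`,
#'   `"count"`, `"test"`, `"report"` (default: everything).
#' @return Invisibly, a list with the main result objects and the manifest.
#' @export
run_apa_pipeline <- function(config, stop_after = "report") {
  if (is.character(config)) config <- read_pipeline_config(config)
  par <- utils::modifyList(apa_defaults(), config)
  stages <- c("regions", "peaks", "count", "test", "report")
  stop_after <- match.arg(stop_after, stages)
  if (!identical(par$caller, "coverage")) {
    stop("alternative peak callers are reserved but not implemented; use caller = 'coverage'",
      call. = FALSE
    )
  }
  for (key in c("bam", "gtf", "fasta", "clusters")) {
    if (is.null(par[[key]])) stop("config misses required path: ", key, call. = FALSE)
    if (!file.exists(par[[key]])) {
      stop("input file for '", key, "' not found: ", par[[key]], call. = FALSE)
    }
  }
  out_dir <- par$out_dir %||% stop("config misses out_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[apatag] ", ...)
  tally <- list()
  t0 <- Sys.time()

  log_msg("stage regions: building 3' UTR and intronic regions")
  utr_regions <- build_utr_regions(par$gtf)
  intron_regions <- build_intron_regions(par$gtf, utr_regions)
  write_regions_bed(utr_regions, file.path(out_dir, "utr_regions.bed"))
  if (nrow(intron_regions) > 0) {
    write_regions_bed(intron_regions, file.path(out_dir, "intron_regions.bed"))
  }
  tally$regions <- list(n_utr = nrow(utr_regions), n_intron = nrow(intron_regions))
  if (stop_after == "regions") {
    return(invisible(.finish_manifest(par, tally, out_dir, t0)))
  }

  log_msg("stage peaks: pooling reads and calling peaks")
  reads <- read_tag_alignments(par$bam, barcode_tag = par$barcode_tag, min_mapq = par$min_mapq)
  pooled <- pool_reads_by_cluster(reads, par$clusters)
  genome <- load_genome(par$fasta)
  raw <- call_peaks(pooled, min_reads = par$min_reads, max_gap = par$max_gap)
  utr_pk <- assign_peaks(raw, utr_regions)
  leftover <- utr_pk |>
    dplyr::filter(is.na(.data$region_id)) |>
    dplyr::select(-"peak_id", -"region_id", -"gene_id", -"peak_index")
  utr_pk <- utr_pk |>
    dplyr::filter(!is.na(.data$region_id)) |>
    split_bimodal_peaks(
      min_split_reads = par$min_split_reads,
      min_distance = par$split_min_distance, sd_factor = par$split_sd_factor
    )
  intron_pk <- if (nrow(intron_regions) > 0 && nrow(leftover) > 0) {
    assign_peaks(leftover, intron_regions) |>
      dplyr::filter(!is.na(.data$region_id)) |>
      split_bimodal_peaks(
        min_split_reads = par$min_split_reads,
        min_distance = par$split_min_distance, sd_factor = par$split_sd_factor
      )
  } else {
    .empty_peaks() |> dplyr::mutate(
      peak_id = character(), region_id = character(),
      gene_id = character(), peak_index = integer(), split = logical()
    )
  }
  peaks_all <- dplyr::bind_rows(utr_pk, intron_pk)
  peaks_all <- scan_pas_motifs(peaks_all, genome)
  if (!is.null(par$reference_bed)) {
    peaks_all <- peak_edge_distance(peaks_all, par$reference_bed)
  }
  write_regions_bed(peaks_all, file.path(out_dir, "peaks.bed"))
  readr::write_tsv(
    dplyr::select(peaks_all, -"member_pos"),
    file.path(out_dir, "peaks_metadata.tsv")
  )
  tally$peaks <- list(
    n_raw = nrow(raw),
    n_utr = nrow(utr_pk), n_utr_split = attr(utr_pk, "n_split"),
    n_intron = nrow(intron_pk),
    pas_prevalence = pas_prevalence(peaks_all)
  )
  if (stop_after == "peaks") {
    return(invisible(.finish_manifest(par, tally, out_dir, t0)))
  }

  log_msg("stage count: counting and filtering")
  utr_counts <- count_reads(utr_pk, pooled)
  utr_filt <- filter_peaks(utr_counts, genome,
    kind = "utr",
    min_cpm = par$min_cpm_utr, a_run = par$a_run_utr, window = par$window_utr
  )
  write_counts_tsv(utr_counts, file.path(out_dir, "utr_peak_counts.tsv"))
  write_counts_tsv(utr_filt, file.path(out_dir, "utr_peak_counts_filtered.tsv"))
  readr::write_tsv(attr(utr_filt, "removed"), file.path(out_dir, "utr_peak_removals.tsv"))
  intron_filt <- NULL
  if (nrow(intron_pk) > 0) {
    intron_counts <- count_reads(intron_pk, pooled)
    intron_filt <- filter_peaks(intron_counts, genome,
      kind = "intron",
      min_cpm = par$min_cpm_intron, min_count = par$min_count_intron,
      a_run = par$a_run_intron, window = par$window_intron
    )
    write_counts_tsv(intron_counts, file.path(out_dir, "intron_peak_counts.tsv"))
    write_counts_tsv(intron_filt, file.path(out_dir, "intron_peak_counts_filtered.tsv"))
    readr::write_tsv(attr(intron_filt, "removed"), file.path(out_dir, "intron_peak_removals.tsv"))
  }
  tally$count <- list(
    n_utr_kept = nrow(utr_filt),
    n_utr_removed = nrow(attr(utr_filt, "removed")),
    n_intron_kept = if (is.null(intron_filt)) 0L else nrow(intron_filt),
    n_intron_removed = if (is.null(intron_filt)) 0L else nrow(attr(intron_filt, "removed"))
  )
  if (stop_after == "count") {
    return(invisible(.finish_manifest(par, tally, out_dir, t0)))
  }

  log_msg("stage test: differential usage statistics")
  pair <- par$pair %||% sort(unique(pooled$cluster))[1:2]
  utr_test <- test_differential_usage(utr_filt, fdr = par$fdr, pair = pair)
  readr::write_tsv(tidy(utr_test), file.path(out_dir, "utr_differential_usage.tsv"))
  sig_multi <- tidy(utr_test) |>
    dplyr::filter(.data$significant, .data$n_peaks > 2)
  if (nrow(sig_multi) > 0) {
    pp <- purrr::map_dfr(sig_multi$utr_id, function(u) {
      per_peak_tests(dplyr::filter(utr_filt, .data$region_id == u))
    })
    readr::write_tsv(pp, file.path(out_dir, "utr_per_peak_tests.tsv"))
  }
  intron_test <- NULL
  if (!is.null(intron_filt) && nrow(intron_filt) > 0) {
    intron_test <- test_intronic_usage(intron_filt, utr_filt, fdr = par$fdr, pair = pair)
    readr::write_tsv(tidy(intron_test), file.path(out_dir, "intronic_differential_usage.tsv"))
  }
  summary_tbl <- glance(utr_test)
  if (!is.null(intron_test)) summary_tbl <- dplyr::bind_rows(summary_tbl, glance(intron_test))
  readr::write_tsv(summary_tbl, file.path(out_dir, "differential_usage_summary.tsv"))
  tally$test <- list(
    n_utr_significant = sum(tidy(utr_test)$significant),
    n_intron_significant = if (is.null(intron_test)) 0L else sum(tidy(intron_test)$significant)
  )
  if (stop_after == "test") {
    return(invisible(.finish_manifest(par, tally, out_dir, t0)))
  }

  log_msg("stage report: expression and per-cell summaries")
  expr <- utr_expression(utr_filt)
  readr::write_tsv(expr, file.path(out_dir, "utr_expression.tsv"))
  cell_counts <- count_reads(utr_pk, pooled, by = "cell")
  cell_counts <- cell_counts[cell_counts$peak_id %in% utr_filt$peak_id, , drop = FALSE]
  cell_pui <- per_cell_mean_pui(cell_counts)
  readr::write_tsv(cell_pui, file.path(out_dir, "per_cell_mean_pui.tsv"))
  tally$report <- list(
    n_utr_expressed = nrow(expr),
    n_cells = nrow(cell_pui)
  )
  manifest <- .finish_manifest(par, tally, out_dir, t0)
  invisible(list(
    utr_regions = utr_regions, intron_regions = intron_regions,
    peaks = peaks_all, utr_counts = utr_filt, intron_counts = intron_filt,
    utr_test = utr_test, intron_test = intron_test,
    expression = expr, per_cell_pui = cell_pui, manifest = manifest
  ))
}

.finish_manifest <- function(par, tally, out_dir, t0) {
  manifest <- list(
    package = "apatag",
    version = as.character(utils::packageVersion("apatag")),
    parameters = par[setdiff(names(par), "pair")],
    pair = par$pair,
    seed = par$seed,
    stages = tally,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  manifest
}
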