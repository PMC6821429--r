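#' Count reads per peak per cluster (or per cell)
#'
#' A read is counted to a peak when its footprint overlaps the peak interval
#' on the same strand. A read overlapping several peaks is assigned to the
#' peak containing its strand-aware 3' end; if none or several contain it,
#' the most proximal candidate wins (reported). Each read is counted at most
#' once.
#'
#' @param peaks Peak tibble (post-splitting), typically from
#'   [split_bimodal_peaks()]; unassigned peaks (`region_id` NA) are dropped.
#' @param reads Read tibble with a `cluster` column from
#'   [pool_reads_by_cluster()] (and `barcode` when `by = "cell"`).
#' @param by Count per `"cluster"` (default) or per `"cell"` barcode.
#' @return A count tibble: peak metadata columns (`peak_id, region_id,
#'   gene_id, peak_index, chrom, start, end, strand, three_prime_edge`)
#'   followed by one integer column per cluster (or cell).
#' @export
count_reads <- function(peaks, reads, by = c("cluster", "cell")) {
  by <- match.arg(by)
  grp_col <- if (by == "cluster") "cluster" else "barcode"
  stopifnot(grp_col %in% names(reads))
  if ("region_id" %in% names(peaks)) {
    peaks <- peaks |> dplyr::filter(!is.na(.data$region_id))
  }
  meta <- peaks |>
    dplyr::select(dplyr::any_of(setdiff(.peak_meta_cols, "n_reads")))
  groups <- sort(unique(reads[[grp_col]]))
  if (nrow(peaks) == 0) {
    for (g in groups) meta[[g]] <- integer(0)
    return(meta)
  }

  pg <- .as_granges(peaks)
  rg <- .as_granges(reads)
  hits <- GenomicRanges::findOverlaps(rg, pg)
  if (length(hits) == 0) {
    counts <- matrix(0L, nrow(peaks), length(groups))
  } else {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    end3 <- .three_prime_edge(reads$start, reads$end, reads$strand)[q]
    contains <- end3 >= peaks$start[s] & end3 <= peaks$end[s]
    ord <- order(q, !contains, peaks$peak_index[s] %||% peaks$start[s])
    sel <- ord[!duplicated(q[ord])]
    multi <- sum(duplicated(q))
    if (multi > 0) {
      message(multi, " read-peak overlap(s) beyond the first were resolved by 3'-end containment")
    }
    counts <- as.matrix(table(
      factor(s[sel], levels = seq_len(nrow(peaks))),
      factor(reads[[grp_col]][q[sel]], levels = groups)
    ))
  }
  for (j in seq_along(groups)) meta[[groups[j]]] <- as.integer(counts[, j])
  meta
}

#' Counts per million per sample column
#'
#' Divides each sample column by its total and scales to one million, the
#' depth normalisation used for peak filtering.
#'
#' @param counts A count tibble from [count_reads()].
#' @return The tibble with sample columns replaced by CPM values.
#' @export
cpm <- function(counts) {
  sc <- sample_cols(counts)
  stopifnot(length(sc) > 0)
  totals <- vapply(counts[sc], sum, numeric(1))
  if (any(totals == 0)) {
    stop(
      "zero-total sample column(s): ", paste(sc[totals == 0], collapse = ", "),
      call. = FALSE
    )
  }
  for (j in seq_along(sc)) {
    counts[[sc[j]]] <- counts[[sc[j]]] / totals[j] * 1e6
  }
  counts
}

#' Filter peaks on usage and internal-priming evidence
#'
#' Two filters, in order. First a usage filter: 3' UTR peaks must exceed a
#' summed CPM of `min_cpm` over all clusters; intronic peaks must additionally
#' reach `min_count` total raw counts (and their CPM rule is inclusive).
#' Second an internal-priming filter: peaks whose downstream sense-strand
#' sequence contains a long adenine run are discarded, because oligo-dT
#' priming at genomically encoded A stretches mimics a pA site. For UTR peaks
#' the scan window is 10-140 nt downstream of the 3' edge and the run length
#' is 8; intronic peaks use the stricter 1-200 nt window and run length 7.
#'
#' @param counts Count tibble from [count_reads()].
#' @param genome `DNAStringSet` or FASTA path.
#' @param kind `"utr"` or `"intron"`; selects thresholds and windows.
#' @param min_cpm Summed-CPM threshold (default 10).
#' @param min_count Total raw count threshold for intronic peaks (default 50).
#' @param a_run Override the A-run length.
#' @param window Override the downstream scan window `c(from, to)` in nt.
#' @return The filtered count tibble; attribute `removed` is a tibble of
#'   `peak_id, reason` with reasons `low_cpm`, `low_count`, `a_run`.
#' @export
filter_peaks <- function(counts, genome, kind = c("utr", "intron"),
                         min_cpm = 10, min_count = 50,
                         a_run = NULL, window = NULL) {
  kind <- match.arg(kind)
  a_run <- a_run %||% if (kind == "utr") 8L else 7L
  window <- window %||% if (kind == "utr") c(10L, 140L) else c(1L, 200L)
  sc <- sample_cols(counts)
  stopifnot(length(sc) > 0)

  cpm_sum <- rowSums(as.matrix(cpm(counts)[sc]))
  count_sum <- rowSums(as.matrix(counts[sc]))
  pass_usage <- if (kind == "utr") {
    cpm_sum > min_cpm
  } else {
    count_sum >= min_count & cpm_sum >= min_cpm
  }
  removed <- tibble::tibble(
    peak_id = counts$peak_id[!pass_usage],
    reason = if (kind == "utr") {
      rep("low_cpm", sum(!pass_usage))
    } else {
      as.character(ifelse(count_sum[!pass_usage] < min_count, "low_count", "low_cpm"))
    }
  )
  kept <- counts[pass_usage, , drop = FALSE]

  if (nrow(kept) > 0) {
    seqs <- .edge_window_seq(
      kept$chrom, kept$three_prime_edge, kept$strand, genome,
      from = window[1], to = window[2]
    )
    priming <- stringr::str_detect(seqs, strrep("A", a_run))
    removed <- dplyr::bind_rows(
      removed,
      tibble::tibble(peak_id = kept$peak_id[priming], reason = "a_run")
    )
    kept <- kept[!priming, , drop = FALSE]
  }
  if (nrow(removed) > 0) {
    message(
      "filter_peaks (", kind, "): removed ", nrow(removed), " peak(s) (",
      paste(names(table(removed$reason)), table(removed$reason),
        sep = "=", collapse = ", "
      ), ")"
    )
  }
  attr(kept, "removed") <- removed
  kept
}

#' Randomly downsample reads
#'
#' Each read is retained independently with probability `fraction`, the
#' empirical depth-robustness device: rerunning the pipeline on the retained
#' subset shows how peak detection depends on sequencing depth.
#'
#' @param reads Read tibble.
#' @param fraction Retention probability in (0, 1].
#' @param seed Optional seed for a private RNG stream.
#' @return The retained subset of `reads`.
#' @export
downsample_reads <- function(reads, fraction, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
    fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single value in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) {
    return(reads)
  }
  draw <- function() stats::runif(nrow(reads)) < fraction
  keep <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  reads[keep, , drop = FALSE]
}

#' Write a count tibble as TSV
#'
#' @param counts Count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(dplyr::select(counts, -dplyr::any_of("member_pos")), path)
  invisible(path)
}
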