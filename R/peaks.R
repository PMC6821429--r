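#' Read aligned 3' tag reads with their cell barcodes
#'
#' Loads primary, uniquely mapped alignments from a SAM or BAM file together
#' with a cell-barcode tag. SAM input is converted on the fly. Records without
#' the barcode tag are dropped and tallied.
#'
#' @param path SAM or BAM file.
#' @param barcode_tag SAM tag holding the cell barcode (default `"CB"`).
#' @param min_mapq Minimum mapping quality kept; the default 255 is the value
#'   STAR-derived pipelines assign to uniquely mapped reads.
#' @return Tibble with `read_id, chrom, start, end, strand, barcode` (1-based
#'   closed coordinates of the aligned footprint).
#' @export
read_tag_alignments <- function(path, barcode_tag = "CB", min_mapq = 255) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq"),
    tag = barcode_tag,
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    )
  )
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  mc <- S4Vectors::mcols(ga)
  bc <- mc[[barcode_tag]]
  if (is.null(bc)) bc <- rep(NA_character_, length(ga))
  keep <- !is.na(mc$mapq) & mc$mapq >= min_mapq
  n_tagless <- sum(is.na(bc[keep]))
  if (n_tagless > 0) {
    message(n_tagless, " record(s) lacked the ", barcode_tag, " tag and were skipped")
  }
  keep <- keep & !is.na(bc)
  tibble::tibble(
    read_id = mc$qname[keep],
    chrom = as.character(GenomicAlignments::seqnames(ga))[keep],
    start = GenomicAlignments::start(ga)[keep],
    end = GenomicAlignments::end(ga)[keep],
    strand = as.character(GenomicAlignments::strand(ga))[keep],
    barcode = bc[keep]
  )
}

#' Pool reads by cell cluster (pseudobulk)
#'
#' Attaches each read's cluster label from a barcode-to-cluster assignment and
#' discards reads whose barcode is not in the assignment (their number is
#' reported and attached as attribute `dropped`).
#'
#' @param reads Read tibble from [read_tag_alignments()] or the simulator.
#' @param clusters Tibble with columns `barcode` and `cluster`, or a TSV/CSV
#'   path with those columns.
#' @return `reads` with a `cluster` column, unassigned reads removed.
#' @export
pool_reads_by_cluster <- function(reads, clusters) {
  if (is.character(clusters)) {
    delim <- if (grepl("\\.csv$", clusters, ignore.case = TRUE)) "," else "\t"
    clusters <- readr::read_delim(clusters,
      delim = delim, show_col_types = FALSE,
      progress = FALSE
    )
  }
  stopifnot(all(c("barcode", "cluster") %in% names(clusters)))
  if (length(intersect(reads$barcode, clusters$barcode)) == 0) {
    stop("no read barcode matches the cluster assignment", call. = FALSE)
  }
  out <- reads |>
    dplyr::select(-dplyr::any_of("cluster")) |>
    dplyr::inner_join(
      dplyr::distinct(clusters[, c("barcode", "cluster")]),
      by = "barcode"
    )
  dropped <- nrow(reads) - nrow(out)
  if (dropped > 0) {
    message(dropped, " read(s) from barcodes without a cluster assignment were dropped")
  }
  tally <- dplyr::count(out, .data$cluster)
  message(
    "pooled reads per cluster: ",
    paste(tally$cluster, tally$n, sep = "=", collapse = ", ")
  )
  attr(out, "dropped") <- dropped
  out
}

#' Call strand-aware coverage peaks
#'
#' Peaks are maximal strand-specific intervals with footprint coverage of at
#' least one read; intervals separated by at most `max_gap` uncovered bases
#' are merged, and intervals supported by fewer than `min_reads` reads are
#' discarded. Every surviving peak records the strand-aware 3' ends of its
#' member reads, the substrate for bimodal splitting and edge benchmarking.
#'
#' @param reads Read tibble (all clusters pooled).
#' @param min_reads Minimum member reads per peak (default 5).
#' @param max_gap Maximum uncovered gap merged across (default 0).
#' @return Tibble with `chrom, start, end, strand, n_reads, three_prime_edge`
#'   and a `member_pos` list-column of member-read 3'-end coordinates.
#' @export
call_peaks <- function(reads, min_reads = 5, max_gap = 0) {
  stopifnot(min_reads >= 1, max_gap >= 0)
  if (nrow(reads) == 0) {
    return(.empty_peaks())
  }
  .assert_strand(reads$strand)
  reads |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(d$start, d$end)
      cov <- IRanges::coverage(ir)
      runs <- IRanges::slice(cov, lower = 1, rangesOnly = TRUE)
      if (max_gap > 0) runs <- IRanges::reduce(runs, min.gapwidth = max_gap + 1L)
      if (length(runs) == 0) {
        return(tibble::tibble())
      }
      hit <- IRanges::findOverlaps(ir, runs, select = "first")
      ends3 <- .three_prime_edge(d$start, d$end, key$strand)
      tibble::tibble(
        start = IRanges::start(runs), end = IRanges::end(runs),
        n_reads = tabulate(hit, nbins = length(runs)),
        member_pos = unname(split(ends3, factor(hit, levels = seq_along(runs))))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_reads >= min_reads) |>
    dplyr::mutate(three_prime_edge = .three_prime_edge(.data$start, .data$end, .data$strand)) |>
    dplyr::select(
      "chrom", "start", "end", "strand", "n_reads",
      "three_prime_edge", "member_pos"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

.empty_peaks <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), n_reads = integer(), three_prime_edge = integer(),
    member_pos = list()
  )
}

#' Assign peaks to 3' UTR or intronic regions
#'
#' A peak is assigned to a region when they overlap by at least one base on
#' the same strand; peak coordinates are not clipped to the region. A peak
#' overlapping regions of different genes goes to the region with the larger
#' overlap (ties to the lexicographically lower region ID, reported). Within
#' each region, peaks are numbered 5' to 3' in transcript orientation, so
#' index 1 is the most proximal peak (on the minus strand, the one with the
#' highest genomic coordinate is numbered last). Unassigned peaks are kept
#' with `region_id = NA`.
#'
#' @param peaks Tibble from [call_peaks()].
#' @param regions Tibble from [build_utr_regions()] or [build_intron_regions()].
#' @return `peaks` with `region_id, gene_id, peak_index, peak_id` added;
#'   rows with `region_id = NA` are the unassigned peaks.
#' @export
assign_peaks <- function(peaks, regions) {
  id_col <- intersect(c("utr_id", "intron_id"), names(regions))[1]
  if (is.na(id_col)) stop("`regions` must carry utr_id or intron_id", call. = FALSE)
  regions <- regions |>
    dplyr::rename(region_id = dplyr::all_of(id_col)) |>
    dplyr::arrange(.data$region_id)
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks,
      region_id = character(), gene_id = character(),
      peak_index = integer(), peak_id = character()
    ))
  }
  pg <- .as_granges(peaks)
  rg <- .as_granges(regions)
  hits <- GenomicRanges::findOverlaps(pg, rg) # strand-matched by default
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(pg)[S4Vectors::queryHits(hits)],
    IRanges::ranges(rg)[S4Vectors::subjectHits(hits)]
  ))
  cand <- tibble::tibble(
    peak = S4Vectors::queryHits(hits),
    region = S4Vectors::subjectHits(hits),
    overlap = ov
  )
  # larger overlap wins; regions pre-sorted by ID so ties take the lower ID
  best <- cand |>
    dplyr::arrange(.data$peak, dplyr::desc(.data$overlap), .data$region) |>
    dplyr::distinct(.data$peak, .keep_all = TRUE)
  if (nrow(cand) > 0) {
    n_tie <- cand |>
      dplyr::group_by(.data$peak) |>
      dplyr::filter(dplyr::n_distinct(.data$region) > 1, .data$overlap == max(.data$overlap)) |>
      dplyr::summarise(tie = dplyr::n() > 1, .groups = "drop")
    if (any(n_tie$tie)) {
      message(sum(n_tie$tie), " peak(s) overlapped two regions equally; lower region ID used")
    }
  }
  peaks$region_id <- NA_character_
  peaks$gene_id <- NA_character_
  peaks$region_id[best$peak] <- regions$region_id[best$region]
  peaks$gene_id[best$peak] <- regions$gene_id[best$region]
  .index_peaks(peaks)
}

# (re)compute proximal indices and peak IDs within regions
.index_peaks <- function(peaks) {
  peaks |>
    dplyr::group_by(.data$region_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      peak_index = dplyr::if_else(
        is.na(.data$region_id),
        NA_integer_,
        # strand is constant within a region
        dplyr::if_else(.data$strand == "+", dplyr::row_number(),
          dplyr::n() - dplyr::row_number() + 1L
        )
      ),
      peak_id = dplyr::if_else(
        is.na(.data$region_id), NA_character_,
        paste0(.data$region_id, "_", .data$peak_index)
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::relocate("peak_id", "region_id", "gene_id", "peak_index") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Fit a two-component Gaussian mixture to read 3'-end positions
#'
#' Plain EM on one-dimensional positions, deterministically initialised at the
#' 25th and 75th percentiles with equal weights and a common starting SD.
#' Used by [split_bimodal_peaks()] to decide whether a peak covers two
#' adjacent pA sites.
#'
#' @param positions Numeric vector of member-read 3'-end coordinates.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @return An object of class `peak_mixture`: component means (`mu1 < mu2`),
#'   SDs, weights, log-likelihood, iteration count, convergence flag, and the
#'   equal-density `boundary` between the means.
#' @export
fit_peak_mixture <- function(positions, max_iter = 500, tol = 1e-6) {
  x <- as.numeric(positions)
  n <- length(x)
  stopifnot(n >= 4)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  mu <- sort(q)
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5)
  s0 <- max(stats::sd(x) / 2, 1)
  sigma <- c(s0, s0)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) {
      degenerate <- TRUE
      break
    }
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    n1 <- sum(g)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) {
      degenerate <- TRUE
      break
    }
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma <- sqrt(c(
      sum(g * (x - mu[1])^2) / n1,
      sum((1 - g) * (x - mu[2])^2) / n2
    ))
    if (any(sigma < 1e-6)) {
      degenerate <- TRUE
      break
    }
    w <- c(n1, n2) / n
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu)
    sigma <- rev(sigma)
    w <- rev(w)
  }
  boundary <- .equal_density_boundary(mu, sigma, w)
  structure(
    list(
      mu1 = mu[1], mu2 = mu[2], sigma1 = sigma[1], sigma2 = sigma[2],
      w1 = w[1], w2 = w[2], loglik = ll_old, iter = iter,
      converged = converged, degenerate = degenerate,
      boundary = boundary, n = n
    ),
    class = "peak_mixture"
  )
}

# coordinate between the means where the weighted component densities cross
.equal_density_boundary <- function(mu, sigma, w) {
  if (mu[1] >= mu[2]) {
    return(mean(mu))
  }
  f <- function(x) {
    log(w[1]) + stats::dnorm(x, mu[1], sigma[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, mu[2], sigma[2], log = TRUE)
  }
  lo <- mu[1]
  hi <- mu[2]
  flo <- f(lo)
  fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    return(mean(mu))
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-3)$root
}

#' Should a fitted peak mixture be split?
#'
#' The split rule requires the two fitted modes to be separated by more than
#' `sd_factor` times the larger component SD and by at least `min_distance`
#' nt. Degenerate or non-converged fits are never split.
#'
#' @param fit A `peak_mixture`.
#' @param min_distance Minimum mode separation in nt (default 75).
#' @param sd_factor Multiplier on the larger component SD (default 3).
#' @return Logical.
#' @export
should_split <- function(fit, min_distance = 75, sd_factor = 3) {
  if (fit$degenerate || !fit$converged) {
    return(FALSE)
  }
  delta <- fit$mu2 - fit$mu1
  delta > sd_factor * max(fit$sigma1, fit$sigma2) && delta >= min_distance
}

#' Split peaks covering two adjacent pA sites
#'
#' Adjacent pA sites can produce one merged coverage peak. For every peak with
#' at least `min_split_reads` member reads, a two-component Gaussian mixture
#' is fitted to the member 3'-end positions; when the modes are separated by
#' more than `sd_factor` fitted SDs and at least `min_distance` nt, the peak
#' is split at the coordinate where the two weighted component densities are
#' equal. Member reads are partitioned by that boundary and each sub-peak's
#' interval is the span of its members. Sub-peaks are re-examined, so a peak
#' merging three sites resolves in two rounds. Proximal indices and peak IDs
#' are recomputed afterwards when region assignments are present.
#'
#' @param peaks Tibble from [call_peaks()] or [assign_peaks()].
#' @param min_split_reads Minimum members to attempt a fit (default 20);
#'   mixture fits on fewer points are unstable, so smaller peaks are never
#'   split.
#' @param min_distance,sd_factor Split rule, see [should_split()].
#' @param max_iter,tol EM controls, see [fit_peak_mixture()].
#' @return The peak tibble with split peaks replaced by their sub-peaks and a
#'   `split` logical column; attribute `n_split` counts executed splits.
#' @export
split_bimodal_peaks <- function(peaks, min_split_reads = 20, min_distance = 75,
                                sd_factor = 3, max_iter = 500, tol = 1e-6) {
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks, split = logical()))
  }
  n_split <- 0L
  split_one <- function(row) {
    pos <- row$member_pos[[1]]
    if (length(pos) < min_split_reads) {
      return(dplyr::mutate(row, split = FALSE))
    }
    fit <- fit_peak_mixture(pos, max_iter = max_iter, tol = tol)
    if (!should_split(fit, min_distance = min_distance, sd_factor = sd_factor)) {
      if (!fit$converged && !fit$degenerate) {
        message("EM did not converge for peak at ", row$chrom, ":", row$start, "; left unsplit")
      }
      return(dplyr::mutate(row, split = FALSE))
    }
    n_split <<- n_split + 1L
    left <- pos[pos <= fit$boundary]
    right <- pos[pos > fit$boundary]
    subs <- purrr::map_dfr(list(left, right), function(m) {
      s <- dplyr::mutate(row,
        start = min(m), end = max(m),
        n_reads = length(m), member_pos = list(m),
        three_prime_edge = .three_prime_edge(min(m), max(m), row$strand),
        split = TRUE
      )
      s
    })
    purrr::map_dfr(seq_len(nrow(subs)), function(i) split_one(subs[i, ]))
  }
  out <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) split_one(peaks[i, ]))
  if ("region_id" %in% names(out)) out <- .index_peaks(out)
  attr(out, "n_split") <- n_split
  out
}

#' Signed distance from peak 3' edges to reference pA sites
#'
#' For each peak, the nearest reference site on the same chromosome and strand
#' is found and the distance is reported in transcript orientation
#' (`reference - edge` on the plus strand, `edge - reference` on the minus
#' strand), so 0 means the edge coincides with the annotated site and positive
#' values mean the reference lies downstream of the edge. Peaks with no
#' same-strand site on their chromosome get `NA`.
#'
#' @param peaks Peak tibble with `three_prime_edge`.
#' @param reference_sites Tibble with `chrom, position, strand`, or a BED file
#'   of single-base sites.
#' @return `peaks` with a `ref_distance` column.
#' @export
peak_edge_distance <- function(peaks, reference_sites) {
  if (is.character(reference_sites)) {
    gr <- rtracklayer::import(reference_sites, format = "BED")
    reference_sites <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      position = GenomicRanges::start(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  }
  stopifnot(all(c("chrom", "position", "strand") %in% names(reference_sites)))
  peaks$ref_distance <- purrr::pmap_dbl(
    peaks[, c("chrom", "strand", "three_prime_edge")],
    function(chrom, strand, three_prime_edge) {
      cand <- reference_sites$position[
        reference_sites$chrom == chrom & reference_sites$strand == strand
      ]
      if (length(cand) == 0) {
        return(NA_real_)
      }
      d <- cand - three_prime_edge
      d <- d[which.min(abs(d))]
      if (strand == "-") -d else d
    }
  )
  peaks
}

#' Scan peak 3'-edge windows for polyadenylation signals
#'
#' Extracts the sense-strand sequence from 30 nt upstream to 120 nt downstream
#' of each peak's 3' edge (clipped at chromosome ends) and scans it for the
#' canonical PAS hexamer AATAAA and its main variant ATTAAA.
#'
#' @param peaks Peak tibble with `three_prime_edge`.
#' @param genome `DNAStringSet` or FASTA path.
#' @param upstream,downstream Window extent around the edge, in nt.
#' @param motifs Hexamers scanned for.
#' @return `peaks` with a logical `pas_hit` column; the overall prevalence is
#'   available via [pas_prevalence()].
#' @export
scan_pas_motifs <- function(peaks, genome, upstream = 30, downstream = 120,
                            motifs = c("AATAAA", "ATTAAA")) {
  seqs <- .edge_window_seq(
    peaks$chrom, peaks$three_prime_edge, peaks$strand, genome,
    from = -upstream, to = downstream
  )
  pat <- paste(motifs, collapse = "|")
  peaks$pas_hit <- stringr::str_detect(seqs, pat)
  peaks
}

#' Fraction of peaks with a PAS hit
#'
#' @param peaks Peak tibble after [scan_pas_motifs()].
#' @return Proportion of peaks whose edge window contains a PAS hexamer.
#' @export
pas_prevalence <- function(peaks) {
  stopifnot("pas_hit" %in% names(peaks))
  mean(peaks$pas_hit)
}

#' @export
print.peak_mixture <- function(x, ...) {
  cat(sprintf(
    "two-component Gaussian mixture on %d positions\n  mu = (%.1f, %.1f), sigma = (%.1f, %.1f), w = (%.2f, %.2f)\n  boundary = %.1f, loglik = %.2f, %s after %d iterations\n",
    x$n, x$mu1, x$mu2, x$sigma1, x$sigma2, x$w1, x$w2, x$boundary,
    x$loglik, if (x$converged) "converged" else "not converged", x$iter
  ))
  invisible(x)
}

#' Tidy a fitted peak mixture
#'
#' @param x A `peak_mixture` from [fit_peak_mixture()].
#' @param ... Unused.
#' @return One row per mixture component with mean, SD and weight.
#' @method tidy peak_mixture
#' @export
tidy.peak_mixture <- function(x, ...) {
  tibble::tibble(
    component = 1:2,
    mean = c(x$mu1, x$mu2),
    sd = c(x$sigma1, x$sigma2),
    weight = c(x$w1, x$w2)
  )
}

#' One-row summary of a fitted peak mixture
#'
#' @inheritParams tidy.peak_mixture
#' @return Tibble with separation, boundary, log-likelihood, iterations,
#'   convergence and the default split decision.
#' @method glance peak_mixture
#' @export
glance.peak_mixture <- function(x, ...) {
  tibble::tibble(
    n = x$n, separation = x$mu2 - x$mu1, boundary = x$boundary,
    loglik = x$loglik, iter = x$iter, converged = x$converged,
    split = should_split(x)
  )
}

#' Plot a fitted peak mixture over the member-position histogram
#'
#' @param object A `peak_mixture`.
#' @param positions The member positions the model was fitted to.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peak_mixture
#' @export
autoplot.peak_mixture <- function(object, positions, ...) {
  df <- tibble::tibble(pos = as.numeric(positions))
  grid <- tibble::tibble(x = seq(min(df$pos), max(df$pos), length.out = 400))
  grid$density <- object$w1 * stats::dnorm(grid$x, object$mu1, object$sigma1) +
    object$w2 * stats::dnorm(grid$x, object$mu2, object$sigma2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 50, fill = "grey80", colour = "grey50"
    ) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$x, y = .data$density),
      colour = "firebrick"
    ) +
    ggplot2::geom_vline(xintercept = object$boundary, linetype = "dashed") +
    ggplot2::labs(
      x = "read 3'-end position", y = "density",
      title = "Peak mixture fit"
    ) +
    ggplot2::theme_minimal()
}
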