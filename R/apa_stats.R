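#' Proximal polyadenylation usage index
#'
#' For a 3' UTR with two or more peaks, quantifies the relative usage of the
#' most proximal pA site as `log2((C1 + 1) / geomean(C + 1))`, where `C1` is
#' the read count of the proximal peak and the geometric mean runs over the
#' pseudocounted counts of all the UTR's peaks (the proximal one included).
#' Positive values mean proximal-site preference, hence a shorter 3' UTR.
#'
#' @param counts Numeric vector of per-peak read counts of one UTR in one
#'   sample, ordered by proximal index (element 1 = proximal peak).
#' @return The proximal PUI (a single number).
#' @export
#' @examples
#' proximal_pui(c(3, 3)) # 0
#' proximal_pui(c(7, 1)) # 1
proximal_pui <- function(counts) {
  if (length(counts) < 2) {
    stop("proximal PUI requires a UTR with at least two peaks", call. = FALSE)
  }
  stopifnot(all(counts >= 0))
  x <- counts + 1
  log2(x[1] / exp(mean(log(x))))
}

#' Intronic polyadenylation usage index
#'
#' `log2((Ci + 1) / (CU + 1))`, where `Ci` is the read count of the intronic
#' peak and `CU` the summed counts of the same gene's downstream 3' UTR peaks
#' in the same sample. Higher values reflect elevated usage of the intronic
#' pA site (premature cleavage). Vectorised.
#'
#' @param ci,cu Non-negative counts.
#' @return `log2((ci + 1) / (cu + 1))`.
#' @export
#' @examples
#' intronic_pui(3, 7) # -1
intronic_pui <- function(ci, cu) {
  stopifnot(all(ci >= 0), all(cu >= 0))
  log2((ci + 1) / (cu + 1))
}

#' Test differential pA-site usage per 3' UTR between clusters
#'
#' For every UTR with at least two (filtered) peaks, a Pearson chi-squared
#' test of independence is run on the raw peaks-by-clusters count table.
#' Clusters with a zero total for that UTR are dropped; UTRs left with fewer
#' than two non-zero peak rows or fewer than two clusters are marked
#' untestable and excluded from the FDR correction. P-values are adjusted by
#' Benjamini-Hochberg across all tested UTRs and calls with `q < fdr` are
#' flagged significant. Per-cluster proximal PUIs are reported, and for
#' significant UTRs with exactly two peaks a shortening/lengthening direction
#' is called for the designated cluster pair.
#'
#' No continuity correction is applied; tables with an expected count below 1
#' are still tested but flagged (`low_expected`).
#'
#' @param counts Filtered UTR count tibble from [filter_peaks()].
#' @param clusters Cluster columns to compare; default all sample columns.
#' @param fdr Significance level on the BH-adjusted q-value (default 0.05).
#' @param pair Length-2 cluster vector for direction calls; defaults to the
#'   first two of `clusters`.
#' @return An object of class `apa_test` whose `results` tibble has one row
#'   per multi-peak UTR: `utr_id, gene_id, n_peaks, chi2, df, p, q,
#'   significant, pui_<cluster>..., direction, testable, low_expected`.
#'   `direction` is `shortened_in_<A>` / `lengthened_in_<A>` relative to the
#'   first cluster of `pair`.
#' @export
test_differential_usage <- function(counts, clusters = NULL, fdr = 0.05,
                                    pair = NULL) {
  clusters <- clusters %||% sample_cols(counts)
  stopifnot(length(clusters) >= 2, all(clusters %in% names(counts)))
  pair <- pair %||% clusters[1:2]
  stopifnot(length(pair) == 2, all(pair %in% clusters))

  res <- counts |>
    dplyr::filter(!is.na(.data$region_id)) |>
    dplyr::group_by(.data$region_id, .data$gene_id) |>
    dplyr::arrange(.data$peak_index, .by_group = TRUE) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::group_modify(function(d, key) {
      m <- as.matrix(d[, clusters, drop = FALSE])
      rownames(m) <- d$peak_id
      pui <- vapply(clusters, function(cl) proximal_pui(d[[cl]]), numeric(1))
      out <- .chisq_table(m[, colSums(m) > 0, drop = FALSE])
      out$n_peaks <- nrow(d)
      for (cl in clusters) out[[paste0("pui_", cl)]] <- pui[[cl]]
      out$pui_a <- pui[[pair[1]]]
      out$pui_b <- pui[[pair[2]]]
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(utr_id = "region_id")

  res$q <- NA_real_
  res$q[res$testable] <- stats::p.adjust(res$p[res$testable], method = "BH")
  res$significant <- !is.na(res$q) & res$q < fdr
  res$direction <- dplyr::case_when(
    res$significant & res$n_peaks == 2 & res$pui_a > res$pui_b ~
      paste0("shortened_in_", pair[1]),
    res$significant & res$n_peaks == 2 & res$pui_a < res$pui_b ~
      paste0("lengthened_in_", pair[1]),
    TRUE ~ NA_character_
  )
  res <- dplyr::select(res, -"pui_a", -"pui_b") |>
    dplyr::relocate(
      "utr_id", "gene_id", "n_peaks", "chi2", "df", "p", "q",
      "significant", "direction"
    )
  structure(
    list(results = res, clusters = clusters, pair = pair, fdr = fdr, kind = "utr"),
    class = "apa_test"
  )
}

# chi-squared on a peaks x clusters matrix, with testability bookkeeping
.chisq_table <- function(m) {
  testable <- ncol(m) >= 2 && sum(rowSums(m) > 0) >= 2
  if (!testable) {
    return(tibble::tibble(
      chi2 = NA_real_, df = NA_integer_, p = NA_real_,
      testable = FALSE, low_expected = NA
    ))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    chi2 = unname(ct$statistic), df = as.integer(ct$parameter),
    p = ct$p.value, testable = TRUE,
    low_expected = any(ct$expected < 1)
  )
}

#' Direction of a two-peak APA change between two clusters
#'
#' An increase of the proximal PUI in cluster A relative to cluster B means
#' relatively higher proximal-site usage, i.e. 3' UTR shortening in A.
#'
#' @param counts_a,counts_b Length-2 count vectors (proximal, distal) for the
#'   two clusters.
#' @return `"shortened_in_A"`, `"lengthened_in_A"`, or `NA` on equality.
#' @export
classify_direction <- function(counts_a, counts_b) {
  if (length(counts_a) != 2 || length(counts_b) != 2) {
    stop("direction calls are defined for two-peak UTRs; use per_peak_tests() otherwise",
      call. = FALSE
    )
  }
  da <- proximal_pui(counts_a)
  db <- proximal_pui(counts_b)
  if (da > db) {
    "shortened_in_A"
  } else if (da < db) {
    "lengthened_in_A"
  } else {
    NA_character_
  }
}

#' One-tailed binomial test for a global shortening/lengthening excess
#'
#' Tests whether significantly more UTRs shortened than lengthened (or vice
#' versa) under the null that both directions are equally likely:
#' `p = P(X >= max(n_short, n_long))` with `X ~ Binomial(n, 1/2)`.
#'
#' @param n_short,n_long Numbers of UTRs called shortened / lengthened.
#' @return Tibble with `n_short, n_long, dominant, p`.
#' @export
#' @examples
#' binomial_direction_test(10, 0) # p = 2^-10
binomial_direction_test <- function(n_short, n_long) {
  stopifnot(n_short >= 0, n_long >= 0, n_short + n_long >= 1)
  n <- n_short + n_long
  k <- max(n_short, n_long)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  tibble::tibble(
    n_short = n_short, n_long = n_long,
    dominant = if (n_short >= n_long) "shortened" else "lengthened",
    p = p
  )
}

#' Compare PUI distributions between clusters
#'
#' Two clusters are compared with a Wilcoxon rank-sum test (one-tailed when a
#' direction is pre-registered via `alternative`), more than two with a
#' Kruskal-Wallis test.
#'
#' @param pui A named list of numeric PUI vectors (one per cluster), or a data
#'   frame with columns `cluster` and `pui`.
#' @param alternative For two groups: `"two.sided"` (default), `"greater"`
#'   (first group shifted up) or `"less"`.
#' @return Tibble with `method, statistic, p`.
#' @export
compare_pui_distributions <- function(pui, alternative = "two.sided") {
  if (is.data.frame(pui)) {
    stopifnot(all(c("cluster", "pui") %in% names(pui)))
    pui <- split(pui$pui, pui$cluster)
  }
  stopifnot(length(pui) >= 2)
  if (any(vapply(pui, length, integer(1)) == 0)) {
    stop("every cluster must contribute at least one PUI value", call. = FALSE)
  }
  if (length(pui) == 2) {
    ht <- stats::wilcox.test(pui[[1]], pui[[2]], alternative = alternative, exact = FALSE)
    tibble::tibble(
      method = "wilcoxon", statistic = unname(ht$statistic), p = ht$p.value
    )
  } else {
    ht <- stats::kruskal.test(pui)
    tibble::tibble(
      method = "kruskal-wallis", statistic = unname(ht$statistic), p = ht$p.value
    )
  }
}

#' Per-peak usage tests within one multi-peak 3' UTR
#'
#' For a UTR with more than two peaks that changes usage globally, each peak
#' is tested separately: a 2 x K chi-squared of that peak's counts against the
#' summed counts of the UTR's other peaks across clusters, BH-corrected within
#' the UTR.
#'
#' @param counts Count tibble rows of one UTR (one row per peak).
#' @param clusters Cluster columns; default all sample columns.
#' @return Tibble with `peak_id, chi2, df, p, q`.
#' @export
per_peak_tests <- function(counts, clusters = NULL) {
  clusters <- clusters %||% sample_cols(counts)
  stopifnot(length(unique(counts$region_id)) == 1, nrow(counts) >= 2)
  counts <- dplyr::arrange(counts, .data$peak_index)
  m <- as.matrix(counts[, clusters, drop = FALSE])
  m <- m[, colSums(m) > 0, drop = FALSE]
  res <- purrr::map_dfr(seq_len(nrow(m)), function(j) {
    tab <- rbind(m[j, ], colSums(m[-j, , drop = FALSE]))
    out <- .chisq_table(tab)
    out$peak_id <- counts$peak_id[j]
    out
  })
  res$q <- NA_real_
  res$q[res$testable] <- stats::p.adjust(res$p[res$testable], method = "BH")
  dplyr::select(res, "peak_id", "chi2", "df", "p", "q")
}

#' Test differential intronic pA-site usage between clusters
#'
#' For every filtered intronic peak, its per-cluster counts `Ci` are compared
#' to `CU`, the per-cluster sum of the same gene's 3' UTR peak counts lying
#' downstream of the intronic peak in transcript orientation, with a 2 x K
#' chi-squared test. BH correction runs across all testable intronic peaks;
#' direction is called from the intronic PUI of the designated cluster pair.
#'
#' @param intron_counts Filtered intronic count tibble (kind `"intron"`).
#' @param utr_counts Filtered UTR count tibble.
#' @param clusters Cluster columns; default the sample columns shared by both.
#' @param fdr Significance level (default 0.05).
#' @param pair Length-2 cluster vector for direction calls.
#' @return An object of class `apa_test` (kind `"intron"`) whose `results`
#'   tibble has one row per intronic peak: `peak_id, gene_id, chi2, df, p, q,
#'   significant, ipui_<cluster>..., direction, testable`. Peaks of genes with
#'   no downstream UTR counts in any cluster are untestable.
#' @export
test_intronic_usage <- function(intron_counts, utr_counts, clusters = NULL,
                                fdr = 0.05, pair = NULL) {
  clusters <- clusters %||% intersect(sample_cols(intron_counts), sample_cols(utr_counts))
  stopifnot(length(clusters) >= 2)
  pair <- pair %||% clusters[1:2]

  res <- purrr::map_dfr(seq_len(nrow(intron_counts)), function(i) {
    pk <- intron_counts[i, ]
    down <- utr_counts |>
      dplyr::filter(
        .data$gene_id == pk$gene_id,
        if (pk$strand == "+") {
          .data$three_prime_edge > pk$three_prime_edge
        } else {
          .data$three_prime_edge < pk$three_prime_edge
        }
      )
    ci <- as.numeric(pk[1, clusters])
    cu <- if (nrow(down) == 0) {
      rep(0, length(clusters))
    } else {
      colSums(as.matrix(down[, clusters, drop = FALSE]))
    }
    ipui <- intronic_pui(ci, cu)
    m <- rbind(ci, cu)
    colnames(m) <- clusters
    out <- if (sum(cu) == 0) {
      tibble::tibble(
        chi2 = NA_real_, df = NA_integer_, p = NA_real_,
        testable = FALSE, low_expected = NA
      )
    } else {
      .chisq_table(m[, colSums(m) > 0, drop = FALSE])
    }
    out$peak_id <- pk$peak_id
    out$gene_id <- pk$gene_id
    for (k in seq_along(clusters)) {
      out[[paste0("ipui_", clusters[k])]] <- unname(ipui[k])
      out[[paste0("ci_", clusters[k])]] <- unname(ci[k])
      out[[paste0("cu_", clusters[k])]] <- unname(cu[k])
    }
    out
  })
  if (nrow(res) == 0) {
    return(structure(
      list(
        results = res, clusters = clusters, pair = pair, fdr = fdr,
        kind = "intron"
      ),
      class = "apa_test"
    ))
  }
  n_untestable <- sum(!res$testable)
  if (n_untestable > 0) {
    message(n_untestable, " intronic peak(s) had no downstream UTR counts and were not testable")
  }
  res$q <- NA_real_
  res$q[res$testable] <- stats::p.adjust(res$p[res$testable], method = "BH")
  res$significant <- !is.na(res$q) & res$q < fdr
  ia <- res[[paste0("ipui_", pair[1])]]
  ib <- res[[paste0("ipui_", pair[2])]]
  res$direction <- dplyr::case_when(
    res$significant & ia > ib ~ paste0("up_in_", pair[1]),
    res$significant & ia < ib ~ paste0("down_in_", pair[1]),
    TRUE ~ NA_character_
  )
  res <- dplyr::relocate(
    res, "peak_id", "gene_id", "chi2", "df", "p", "q",
    "significant", "direction"
  )
  structure(
    list(results = res, clusters = clusters, pair = pair, fdr = fdr, kind = "intron"),
    class = "apa_test"
  )
}

#' Mean proximal PUI per cell
#'
#' For each cell, averages the proximal PUI over all multi-peak 3' UTRs
#' covered by at least one read in that cell; cells with no qualifying UTR get
#' `NA`. Despite the shallow per-cell coverage of tag libraries this mean
#' tracks the cluster-level APA state of individual cells.
#'
#' @param cell_counts Per-cell count tibble from
#'   `count_reads(peaks, reads, by = "cell")`, restricted to filtered peaks.
#' @return Tibble with `barcode, mean_pui, n_utrs`.
#' @export
per_cell_mean_pui <- function(cell_counts) {
  cells <- sample_cols(cell_counts)
  multi <- cell_counts |>
    dplyr::filter(!is.na(.data$region_id)) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::arrange(.data$peak_index, .by_group = TRUE)
  utrs <- dplyr::group_split(multi)
  purrr::map_dfr(cells, function(bc) {
    puis <- purrr::map_dbl(utrs, function(d) {
      cc <- d[[bc]]
      if (sum(cc) >= 1) proximal_pui(cc) else NA_real_
    })
    ok <- !is.na(puis)
    tibble::tibble(
      barcode = bc,
      mean_pui = if (any(ok)) mean(puis[ok]) else NA_real_,
      n_utrs = sum(ok)
    )
  })
}

# ---- apa_test methods --------------------------------------------------------

#' @export
print.apa_test <- function(x, ...) {
  r <- x$results
  cat(sprintf(
    "APA differential usage (%s): %d unit(s), %d testable, %d significant at q < %g\n",
    x$kind, nrow(r), sum(r$testable %||% FALSE),
    sum(r$significant %||% FALSE), x$fdr
  ))
  invisible(x)
}

#' Tidy an APA test result
#'
#' @param x An `apa_test` from [test_differential_usage()] or
#'   [test_intronic_usage()].
#' @param ... Unused.
#' @return The per-UTR (or per-intronic-peak) results tibble.
#' @method tidy apa_test
#' @export
tidy.apa_test <- function(x, ...) {
  x$results
}

#' One-row summary of an APA test result
#'
#' Counts tested and significant units, tallies direction calls for the
#' designated cluster pair, and reports the one-tailed binomial p-value for
#' the dominant direction.
#'
#' @inheritParams tidy.apa_test
#' @return A one-row tibble.
#' @method glance apa_test
#' @export
glance.apa_test <- function(x, ...) {
  r <- x$results
  dirs <- r$direction[!is.na(r$direction)]
  up <- sum(grepl("^(shortened|up)_", dirs))
  down <- sum(grepl("^(lengthened|down)_", dirs))
  binom <- if (up + down >= 1) binomial_direction_test(up, down)$p else NA_real_
  tibble::tibble(
    kind = x$kind,
    n = nrow(r),
    n_testable = sum(r$testable, na.rm = TRUE),
    n_significant = sum(r$significant, na.rm = TRUE),
    n_up = up, n_down = down,
    binomial_p = binom
  )
}

#' Volcano-style plot of an APA test
#'
#' Plots the PUI difference between the designated cluster pair against the
#' BH-adjusted q-value, colouring significant calls by direction.
#'
#' @param object An `apa_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot apa_test
#' @export
autoplot.apa_test <- function(object, ...) {
  r <- object$results
  pre <- if (object$kind == "utr") "pui_" else "ipui_"
  a <- r[[paste0(pre, object$pair[1])]]
  b <- r[[paste0(pre, object$pair[2])]]
  df <- tibble::tibble(
    delta = a - b, q = r$q,
    direction = dplyr::coalesce(r$direction, "not significant")
  )
  df <- df[!is.na(df$q), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta, y = -log10(pmax(.data$q, 1e-300)),
    colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$fdr), linetype = "dashed") +
    ggplot2::labs(
      x = sprintf(
        "%sPUI(%s) - %sPUI(%s)",
        if (object$kind == "utr") "proximal " else "intronic ",
        object$pair[1], "", object$pair[2]
      ),
      y = "-log10 q", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Empirical cumulative PUI distributions per cluster
#'
#' The standard display for a global APA shift: one ECDF of per-UTR proximal
#' PUI values per cluster; a left-shifted curve marks proximal-site
#' attenuation (longer 3' UTRs).
#'
#' @param x An `apa_test` from [test_differential_usage()].
#' @param significant_only Restrict to significant UTRs (default TRUE).
#' @return A ggplot.
#' @export
plot_pui_ecdf <- function(x, significant_only = TRUE) {
  stopifnot(inherits(x, "apa_test"), x$kind == "utr")
  r <- x$results
  if (significant_only) r <- r[r$significant %in% TRUE, ]
  long <- tidyr::pivot_longer(
    r, dplyr::all_of(paste0("pui_", x$clusters)),
    names_to = "cluster", values_to = "pui", names_prefix = "pui_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pui, colour = .data$cluster)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(
      x = "proximal PUI", y = "cumulative fraction", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data :=
NULL
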