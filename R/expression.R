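#' UTR-level expression from peak counts
#'
#' Sums the counts of all peaks of each 3' UTR per cluster, converts each
#' cluster column to CPM, and quantile-normalises across clusters so every
#' column shares the same value distribution (ties receive the average of the
#' target values over the tied ranks; the target distribution is the row-wise
#' mean of the sorted columns).
#'
#' @param counts Filtered UTR count tibble from [filter_peaks()].
#' @return A tibble with `utr_id`, `gene_id` and one normalised expression
#'   column per cluster.
#' @export
utr_expression <- function(counts) {
  sc <- sample_cols(counts)
  stopifnot(length(sc) >= 1)
  summed <- counts |>
    dplyr::filter(!is.na(.data$region_id)) |>
    dplyr::group_by(utr_id = .data$region_id, gene_id = .data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sc), sum), .groups = "drop")
  m <- as.matrix(summed[, sc, drop = FALSE])
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop(
      "zero-total cluster column(s): ", paste(sc[totals == 0], collapse = ", "),
      call. = FALSE
    )
  }
  m <- sweep(m, 2, totals, "/") * 1e6
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- summed[, c("utr_id", "gene_id")]
  for (j in seq_along(sc)) out[[sc[j]]] <- qn[, j]
  out
}
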