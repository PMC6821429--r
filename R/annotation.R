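#' Build disjoint per-gene 3' UTR regions from a transcript annotation
#'
#' A gene can have transcripts with different annotated 3' UTRs, and different
#' transcripts often share one. This collapses all annotated 3' UTRs of a gene
#' into a set of maximal, non-overlapping regions. A 3' UTR whose annotation
#' spans more than one exon is first truncated, per transcript, to its last
#' (3'-most, strand-aware) exon. Region IDs `<gene_id>:<k>` are serial 5' to 3'
#' in transcript orientation, so `:1` is always the most proximal region.
#'
#' 3' UTR intervals are taken from explicit `three_prime_utr` features when the
#' annotation has them, and otherwise derived per transcript as the exonic
#' sequence strictly 3' of the CDS end. Transcripts with no resolvable 3' UTR
#' are skipped (their number is reported); genes with contradictory strands or
#' spanning several chromosomes are skipped with a warning.
#'
#' @param annotation Path to a GTF file (GENCODE dialect), a `GRanges` as
#'   returned by `rtracklayer::import()`, or a data frame with columns
#'   `chrom,start,end,strand,type,gene_id,transcript_id` (1-based closed
#'   coordinates).
#' @return A tibble with columns `utr_id, gene_id, chrom, start, end, strand`;
#'   coordinates are 1-based closed. Regions of one gene are pairwise disjoint.
#' @export
#' @examples
#' anno <- tibble::tibble(
#'   chrom = "chr1", start = c(1, 101, 1, 101), end = c(50, 200, 50, 150),
#'   strand = "+", type = c("exon", "exon", "CDS", "CDS"),
#'   gene_id = "g1", transcript_id = "t1"
#' )
#' build_utr_regions(anno)
build_utr_regions <- function(annotation) {
  feats <- .load_annotation(annotation)

  utr <- .per_transcript_utr(feats)
  n_tx <- length(unique(feats$transcript_id[feats$type == "exon"]))
  n_with <- length(unique(utr$transcript_id))
  if (n_with < n_tx) {
    message(n_tx - n_with, " transcript(s) had no resolvable 3' UTR and were skipped")
  }
  if (nrow(utr) == 0) {
    return(tibble::tibble(
      utr_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }

  # last-exon truncation per transcript: keep only the 3'-most UTR piece
  utr <- utr |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::filter(
      if (dplyr::first(.data$strand) == "+") .data$start == max(.data$start)
      else .data$end == min(.data$end)
    ) |>
    dplyr::ungroup()

  utr <- .drop_inconsistent_genes(utr)

  .merge_regions_per_gene(utr, id_sep = ":")
}

#' Build per-gene intronic regions free of any 3' UTR
#'
#' Introns are the inter-exon gaps of each transcript, merged per gene. Any
#' part of an intron that overlaps a 3' UTR region of any gene (either strand)
#' is clipped out; introns fully inside a UTR region vanish. Partial overlaps
#' are clipped rather than discarding the whole intron, so true intronic
#' sequence far from any UTR is retained. IDs `<gene_id>:I<k>` are serial 5'
#' to 3' in transcript orientation.
#'
#' @inheritParams build_utr_regions
#' @param utr_regions Tibble from [build_utr_regions()].
#' @return A tibble with columns `intron_id, gene_id, chrom, start, end, strand`.
#' @export
build_intron_regions <- function(annotation, utr_regions) {
  feats <- .load_annotation(annotation)
  exons <- feats |> dplyr::filter(.data$type == "exon")

  introns <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(
      gene_id = .data$gene_id[-1], chrom = .data$chrom[-1],
      strand = .data$strand[-1],
      istart = .data$end[-dplyr::n()] + 1L, iend = .data$start[-1] - 1L
    ) |>
    dplyr::filter(.data$istart <= .data$iend) |>
    dplyr::rename(start = "istart", end = "iend")

  if (nrow(introns) == 0) {
    return(tibble::tibble(
      intron_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }

  introns <- .drop_inconsistent_genes(introns)
  merged <- .merge_regions_per_gene(introns, id_sep = ":I")

  # subtract every UTR region, strand-blind, clipping partial overlaps
  if (nrow(utr_regions) > 0) {
    igr <- .as_granges(merged)
    ugr <- .as_granges(utr_regions)
    # a GRanges setdiff would lose per-gene identity; subtract row-wise instead
    hits <- GenomicRanges::findOverlaps(igr, ugr, ignore.strand = TRUE)
    merged <- .subtract_rowwise(merged, utr_regions, hits)
  }

  merged |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      .k = dplyr::if_else(.data$strand == "+", dplyr::row_number(),
        dplyr::n() - dplyr::row_number() + 1L
      ),
      intron_id = paste0(.data$gene_id, ":I", .data$.k)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("intron_id", "gene_id", "chrom", "start", "end", "strand") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write genomic regions as a BED6 file
#'
#' Coordinates are converted to BED's 0-based half-open convention; the name
#' column carries the region or peak ID, the score column is 0, and the strand
#' column is populated.
#'
#' @param regions Tibble with `chrom,start,end,strand` and an ID column
#'   (`utr_id`, `intron_id` or `peak_id`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  id_col <- intersect(c("utr_id", "intron_id", "peak_id"), names(regions))[1]
  if (is.na(id_col)) stop("no ID column found in `regions`", call. = FALSE)
  gr <- .as_granges(regions)
  gr$name <- regions[[id_col]]
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# ---- internals ---------------------------------------------------------------

.load_annotation <- function(annotation) {
  if (is.character(annotation)) {
    if (!file.exists(annotation)) {
      stop("annotation file not found: ", annotation, call. = FALSE)
    }
    annotation <- rtracklayer::import(annotation, format = "gtf")
  }
  if (inherits(annotation, "GRanges")) {
    annotation <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      strand = as.character(GenomicRanges::strand(annotation)),
      type = as.character(annotation$type),
      gene_id = as.character(annotation$gene_id),
      transcript_id = as.character(annotation$transcript_id)
    )
  }
  need <- c("chrom", "start", "end", "strand", "type", "gene_id", "transcript_id")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0) {
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  .assert_strand(annotation$strand[annotation$type %in% c("exon", "CDS", "three_prime_utr")])
  tibble::as_tibble(annotation[need])
}

# Per-transcript 3' UTR intervals: explicit three_prime_utr features if
# present, otherwise exon pieces strictly 3' of the transcript's CDS end.
.per_transcript_utr <- function(feats) {
  explicit <- feats |> dplyr::filter(.data$type == "three_prime_utr")
  if (nrow(explicit) > 0) {
    return(explicit)
  }
  cds_end <- feats |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      cds_edge = if (dplyr::first(.data$strand) == "+") max(.data$end) else min(.data$start),
      .groups = "drop"
    )
  feats |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::inner_join(cds_end, by = "transcript_id") |>
    dplyr::mutate(
      start = ifelse(.data$strand == "+", pmax(.data$start, .data$cds_edge + 1L), .data$start),
      end = ifelse(.data$strand == "-", pmin(.data$end, .data$cds_edge - 1L), .data$end)
    ) |>
    dplyr::filter(.data$start <= .data$end) |>
    dplyr::select(-"cds_edge")
}

.drop_inconsistent_genes <- function(df) {
  bad <- df |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_strand = dplyr::n_distinct(.data$strand),
      n_chrom = dplyr::n_distinct(.data$chrom), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_strand > 1 | .data$n_chrom > 1)
  if (nrow(bad) > 0) {
    warning(
      "skipping gene(s) with inconsistent strand or chromosome: ",
      paste(bad$gene_id, collapse = ", "),
      call. = FALSE
    )
    df <- df |> dplyr::filter(!.data$gene_id %in% bad$gene_id)
  }
  df
}

# Union intervals per gene and assign serial IDs in transcript orientation.
.merge_regions_per_gene <- function(df, id_sep) {
  merged <- df |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::group_modify(function(d, key) {
      red <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      tibble::tibble(start = IRanges::start(red), end = IRanges::end(red))
    }) |>
    dplyr::ungroup()
  id_col <- if (id_sep == ":") "utr_id" else "intron_id"
  merged |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      # strand is constant within a gene after consistency filtering
      .k = dplyr::if_else(.data$strand == "+", dplyr::row_number(),
        dplyr::n() - dplyr::row_number() + 1L
      ),
      !!id_col := paste0(.data$gene_id, id_sep, .data$.k)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(id_col), "gene_id", "chrom", "start", "end", "strand") |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Subtract overlapping UTR pieces from each intron row independently so the
# gene identity of every surviving piece is retained.
.subtract_rowwise <- function(introns, utrs, hits) {
  if (length(hits) == 0) {
    return(introns)
  }
  hit_introns <- unique(S4Vectors::queryHits(hits))
  keep <- introns[-hit_introns, , drop = FALSE]
  pieces <- purrr::map_dfr(hit_introns, function(i) {
    js <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    left <- IRanges::setdiff(
      IRanges::IRanges(introns$start[i], introns$end[i]),
      IRanges::IRanges(utrs$start[js], utrs$end[js])
    )
    if (length(left) == 0) {
      return(tibble::tibble())
    }
    tibble::tibble(
      intron_id = introns$intron_id[i], gene_id = introns$gene_id[i],
      chrom = introns$chrom[i], start = IRanges::start(left),
      end = IRanges::end(left), strand = introns$strand[i]
    )
  })
  dplyr::bind_rows(keep, pieces)
}
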