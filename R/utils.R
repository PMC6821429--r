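# Internal helpers shared across modules.

# Metadata columns carried by peak tibbles and count tibbles; every other
# column of a count tibble is a sample column (cluster label or cell barcode).
.peak_meta_cols <- c(
  "peak_id", "region_id", "gene_id", "peak_index",
  "chrom", "start", "end", "strand", "three_prime_edge", "n_reads"
)

#' Sample (cluster or cell) columns of a count tibble
#'
#' Count tibbles produced by [count_reads()] keep peak metadata in a fixed set
#' of columns; all remaining columns hold per-cluster (or per-cell) counts.
#'
#' @param counts A count tibble.
#' @return Character vector of sample column names.
#' @export
sample_cols <- function(counts) {
  setdiff(names(counts), .peak_meta_cols)
}

# Convert a tibble with chrom/start/end/strand into a GRanges.
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
}

# Strand-aware 3' terminal base of an interval (1-based closed coords).
# strand may be scalar or vector; result always matches the interval length.
.three_prime_edge <- function(start, end, strand) {
  plus <- rep_len(strand == "+", length(start))
  ifelse(plus, end, start)
}

.assert_strand <- function(strand) {
  bad <- setdiff(unique(strand), c("+", "-"))
  if (length(bad) > 0) {
    stop("strand must be '+' or '-', found: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# Extract the sense-strand sequence of windows around peak edges, clipping to
# chromosome bounds. `genome` is a named DNAStringSet (or path to FASTA).
# Offsets are in transcript orientation: positive = downstream of the edge.
.edge_window_seq <- function(chrom, edge, strand, genome, from, to) {
  genome <- load_genome(genome)
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  gstart <- ifelse(strand == "+", edge + from, edge - to)
  gend <- ifelse(strand == "+", edge + to, edge - from)
  gstart <- pmax(gstart, 1L)
  gend <- pmin(gend, chrlen[chrom])
  keep <- gstart <= gend
  out <- character(length(chrom))
  if (any(keep)) {
    seqs <- Biostrings::subseq(genome[chrom[keep]], gstart[keep], gend[keep])
    rev <- strand[keep] == "-"
    if (any(rev)) seqs[rev] <- Biostrings::reverseComplement(seqs[rev])
    out[keep] <- as.character(seqs)
  }
  out
}

#' Load a genome as a DNAStringSet
#'
#' Accepts a `DNAStringSet` (returned unchanged) or a path to a FASTA file.
#' Sequence names are truncated at the first whitespace, as aligners do.
#'
#' @param genome A `Biostrings::DNAStringSet` or FASTA path.
#' @return A named `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(genome)
  }
  x <- Biostrings::readDNAStringSet(genome)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
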