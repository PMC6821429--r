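#' Configuration for a synthetic 3' tag scRNA-seq experiment
#'
#' Builds the parameter set for [simulate_reference()] and [simulate_reads()].
#' The generator emulates the library model of 3' tag protocols: oligo-dT
#' priming anchors a cDNA fragment at the cleavage/polyadenylation (pA) site,
#' the fragment length is drawn from a truncated normal, and the sequenced read
#' covers the fragment's 5'-most `read_length` bases, so read 3' ends pile up
#' just upstream of the pA site. A configurable fraction of reads instead
#' originates from internal priming at planted genomic A-rich decoys.
#'
#' @param n_genes Number of simulated genes (default 60).
#' @param clusters Character vector of cell-cluster labels.
#' @param pa_sites_per_utr pA sites per 3' UTR, 1-3; scalar or length-`n_genes`.
#' @param site_spacing Distance in nt between consecutive pA sites of a UTR.
#' @param usage_by_cluster Named list (one element per cluster) of usage
#'   proportions over the UTR pA sites, applied to every gene with that many
#'   sites; `NULL` uses the defaults: with two sites, 0.3/0.7 proximal/distal
#'   in the first cluster and 0.7/0.3 in the second (a proximal shift).
#' @param n_cells_per_cluster Cells per cluster (default 100).
#' @param reads_per_cell Mean reads per cell, Poisson distributed (default 1050,
#'   giving the default experiment about 210 thousand reads).
#' @param fragment_mean,fragment_sd Mean and SD (nt) of the cDNA fragment
#'   length; defaults 250 and 50, typical of tag libraries.
#' @param fragment_max Upper size-selection bound on fragment length (nt).
#' @param read_length Read length in nt (default 100).
#' @param internal_priming_rate Probability that a read originates from the
#'   gene's planted A-rich decoy instead of a true pA site.
#' @param planted_pas Plant the canonical AATAAA hexamer ending 20 nt upstream
#'   of every true pA site (sense strand)?
#' @param intronic_pa_fraction Fraction of genes carrying an intronic pA site.
#' @param intronic_usage Per-cluster probability that a (non-artifact) read of
#'   an intronic-pA gene uses the intronic site; recycled over clusters.
#' @param seed Integer seed; all stochastic choices derive from it.
#' @return A list of class `apa_sim_config`.
#' @export
sim_config <- function(n_genes = 60,
                       clusters = c("naive", "activated"),
                       pa_sites_per_utr = 2,
                       site_spacing = 400,
                       usage_by_cluster = NULL,
                       n_cells_per_cluster = 100,
                       reads_per_cell = 1050,
                       fragment_mean = 250,
                       fragment_sd = 50,
                       fragment_max = 400,
                       read_length = 100,
                       internal_priming_rate = 0.05,
                       planted_pas = TRUE,
                       intronic_pa_fraction = 0.25,
                       intronic_usage = c(0.15, 0.30),
                       seed = 1L) {
  stopifnot(
    n_genes >= 1, length(clusters) >= 1, !anyDuplicated(clusters),
    all(pa_sites_per_utr %in% 1:3), site_spacing >= 50,
    fragment_mean > read_length, fragment_max >= read_length,
    internal_priming_rate >= 0, internal_priming_rate < 1,
    intronic_pa_fraction >= 0, intronic_pa_fraction <= 1
  )
  n_sites <- rep_len(as.integer(pa_sites_per_utr), n_genes)
  if (!is.null(usage_by_cluster)) {
    stopifnot(
      length(usage_by_cluster) == length(clusters),
      all(vapply(usage_by_cluster, function(p) {
        abs(sum(p) - 1) < 1e-9 && all(p >= 0)
      }, logical(1)))
    )
    names(usage_by_cluster) <- clusters
  }
  structure(
    list(
      n_genes = as.integer(n_genes), clusters = clusters,
      n_sites = n_sites, site_spacing = as.integer(site_spacing),
      usage_by_cluster = usage_by_cluster,
      n_cells_per_cluster = as.integer(n_cells_per_cluster),
      reads_per_cell = reads_per_cell,
      fragment_mean = fragment_mean, fragment_sd = fragment_sd,
      fragment_max = as.integer(fragment_max),
      read_length = as.integer(read_length),
      internal_priming_rate = internal_priming_rate,
      planted_pas = isTRUE(planted_pas),
      intronic_pa_fraction = intronic_pa_fraction,
      intronic_usage = intronic_usage,
      seed = as.integer(seed)
    ),
    class = "apa_sim_config"
  )
}

# default usage proportions over k sites for cluster index i: clusters
# alternate between a distal-biased and a proximal-biased profile
.default_usage <- function(k, i) {
  base <- switch(as.character(k),
    "1" = 1,
    "2" = c(0.3, 0.7),
    "3" = c(0.2, 0.3, 0.5)
  )
  if (i %% 2 == 0) rev(base) else base
}

.usage_for <- function(config, cluster_idx, k) {
  if (is.null(config$usage_by_cluster)) {
    return(.default_usage(k, cluster_idx))
  }
  p <- config$usage_by_cluster[[cluster_idx]]
  if (length(p) != k) {
    stop("usage_by_cluster entries must have one proportion per pA site", call. = FALSE)
  }
  p
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# fixed gene geometry, in transcript-orientation offsets from the gene 5' end
.sim_geometry <- function(config) {
  list(
    exon1_len = 400L, intron_len = 800L, cds2_len = 200L,
    utr_lead = 350L, # distance from UTR start to the first pA site
    decoy_gap = 500L, # distance from the last true site to the decoy site
    decoy_run_offset = 30L, # A-run placement downstream of the decoy site
    decoy_run_len = 12L,
    utr_tail = 250L, # clean sequence retained past the decoy
    intron_site_offset = 500L, # intronic pA site, from intron start
    gap = 500L, # intergenic spacing
    genes_per_chrom = 25L
  )
}

#' Simulate a reference genome, annotation and pA-site ground truth
#'
#' Generates random-base chromosomes whose background is scrubbed of A (and T)
#' runs of five or more, so that the only A-rich stretches are the planted
#' internal-priming decoys. Genes alternate strand and each carries one
#' two-exon transcript: a coding first exon, one intron, and a last exon whose
#' 3' UTR contains the configured pA sites. AATAAA is planted ending 20 nt
#' upstream of each true site when `planted_pas` is set, and an A-run decoy is
#' planted downstream of the 3'-most site of every gene.
#'
#' @param config An `apa_sim_config` from [sim_config()].
#' @param dir Optional directory; when given, `genome.fa`, `annotation.gtf`
#'   and truth tables (TSV) are written there.
#' @return A list with `genome` (`DNAStringSet`), `annotation` (feature
#'   tibble), `genes`, `sites` and `usage` truth tibbles, and `paths` when
#'   files were written.
#' @export
simulate_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "apa_sim_config"))
  geo <- .sim_geometry(config)
  .with_seed(config$seed, {
    genes <- .layout_genes(config, geo)
    genome <- .build_genome(genes, config, geo)
    anno <- .build_annotation(genes, geo)
    sites <- .site_table(genes, config, geo)
    usage <- .usage_table(genes, config)
    out <- list(
      genome = genome, annotation = anno, genes = genes,
      sites = sites, usage = usage
    )
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      fa <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(genome, fa)
      gtf <- file.path(dir, "annotation.gtf")
      .write_gtf(anno, gtf)
      readr::write_tsv(genes, file.path(dir, "truth_genes.tsv"))
      readr::write_tsv(sites, file.path(dir, "truth_sites.tsv"))
      readr::write_tsv(usage, file.path(dir, "truth_usage.tsv"))
      out$paths <- list(
        genome = fa, annotation = gtf,
        genes = file.path(dir, "truth_genes.tsv"),
        sites = file.path(dir, "truth_sites.tsv"),
        usage = file.path(dir, "truth_usage.tsv")
      )
    }
    out
  })
}

.layout_genes <- function(config, geo) {
  n <- config$n_genes
  utr_len <- geo$utr_lead + (config$n_sites - 1L) * config$site_spacing +
    geo$decoy_gap + geo$utr_tail
  gene_len <- geo$exon1_len + geo$intron_len + geo$cds2_len + utr_len
  chrom_idx <- (seq_len(n) - 1L) %/% geo$genes_per_chrom + 1L
  strand <- rep_len(c("+", "-"), n)
  has_intronic <- seq_len(n) <= round(config$intronic_pa_fraction * n)
  start <- integer(n)
  for (i in seq_len(n)) {
    prev <- which(chrom_idx == chrom_idx[i] & seq_len(n) < i)
    start[i] <- if (length(prev) == 0) {
      geo$gap + 1L
    } else {
      max(start[prev] + gene_len[prev]) + geo$gap
    }
  }
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = paste0("chr", chrom_idx),
    strand = strand,
    gene_start = start,
    gene_end = start + gene_len - 1L,
    gene_len = gene_len,
    n_sites = config$n_sites,
    has_intronic = has_intronic
  )
}

# transcript offset (0-based from the gene 5' end) -> genomic coordinate
# strand may be scalar or vector; result always matches the offset length.
.tx2g <- function(gene_start, gene_end, strand, offset) {
  plus <- rep_len(strand == "+", length(offset))
  ifelse(plus, gene_start + offset, gene_end - offset)
}

.site_table <- function(genes, config, geo) {
  geo_utr0 <- geo$exon1_len + geo$intron_len + geo$cds2_len # UTR start offset
  per_gene <- purrr::pmap_dfr(genes, function(...) {
    g <- list(...)
    k <- g$n_sites
    utr_off <- geo_utr0 + geo$utr_lead - 1L + (seq_len(k) - 1L) * config$site_spacing
    rows <- tibble::tibble(
      gene_id = g$gene_id, site_type = "utr", site_index = seq_len(k),
      tx_offset = utr_off
    )
    decoy_off <- utr_off[k] + geo$decoy_gap
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      gene_id = g$gene_id, site_type = "decoy", site_index = 1L,
      tx_offset = decoy_off
    ))
    if (g$has_intronic) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        gene_id = g$gene_id, site_type = "intron", site_index = 1L,
        tx_offset = geo$exon1_len + geo$intron_site_offset - 1L
      ))
    }
    rows$chrom <- g$chrom
    rows$strand <- g$strand
    rows$position <- .tx2g(g$gene_start, g$gene_end, g$strand, rows$tx_offset)
    # upstream room for an unspliced fragment ending at the site
    feature_start <- dplyr::case_when(
      rows$site_type == "intron" ~ geo$exon1_len,
      TRUE ~ geo_utr0 - geo$cds2_len # last exon start
    )
    rows$max_frag <- pmin(config$fragment_max, rows$tx_offset - feature_start + 1L)
    rows
  })
  per_gene
}

.usage_table <- function(genes, config) {
  purrr::pmap_dfr(genes, function(...) {
    g <- list(...)
    purrr::imap_dfr(config$clusters, function(cl, i) {
      p <- .usage_for(config, i, g$n_sites)
      tibble::tibble(
        gene_id = g$gene_id, cluster = cl,
        site_index = seq_len(g$n_sites), proportion = p,
        intronic_proportion = if (g$has_intronic) {
          rep_len(config$intronic_usage, length(config$clusters))[i]
        } else {
          0
        }
      )
    })
  })
}

.build_genome <- function(genes, config, geo) {
  chroms <- unique(genes$chrom)
  seqs <- lapply(chroms, function(ch) {
    len <- max(genes$gene_end[genes$chrom == ch]) + geo$gap
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    s <- .scrub_runs(s, "A", 4L)
    s <- .scrub_runs(s, "T", 4L)
    s
  })
  names(seqs) <- chroms
  # plant PAS hexamers and decoy A-runs
  sites <- .site_table(genes, config, geo)
  sites <- dplyr::left_join(sites,
    genes[, c("gene_id", "gene_start", "gene_end")],
    by = "gene_id"
  )
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    ch <- st$chrom
    if (st$site_type == "decoy") {
      run <- strrep("A", geo$decoy_run_len)
      seqs[[ch]] <- .plant_motif(
        seqs[[ch]], st$strand, st$gene_start, st$gene_end,
        st$tx_offset + geo$decoy_run_offset, run
      )
    } else if (config$planted_pas) {
      # hexamer occupies transcript offsets [site-25, site-20]: its last base
      # sits 20 nt upstream of the cleavage position
      seqs[[ch]] <- .plant_motif(
        seqs[[ch]], st$strand, st$gene_start, st$gene_end,
        st$tx_offset - 25L, "AATAAA"
      )
    }
  }
  Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
}

# break homopolymer runs of `base` longer than `keep` by substitution
.scrub_runs <- function(s, base, keep) {
  r <- rle(s == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths > keep)
  for (j in long) {
    brk <- seq(starts[j] + keep, ends[j], by = keep + 1L)
    s[brk] <- "G"
  }
  s
}

# write a sense-strand motif starting at a transcript offset into the genome
.plant_motif <- function(seqvec, strand, gene_start, gene_end, tx_start, motif) {
  bases <- strsplit(motif, "")[[1]]
  n <- length(bases)
  if (strand == "+") {
    at <- gene_start + tx_start + seq_len(n) - 1L
    seqvec[at] <- bases
  } else {
    at <- gene_end - tx_start - seq_len(n) + 1L # descending genomic positions
    comp <- chartr("ACGT", "TGCA", bases)
    seqvec[at] <- comp
  }
  seqvec
}

.build_annotation <- function(genes, geo) {
  purrr::pmap_dfr(genes, function(...) {
    g <- list(...)
    e1 <- c(0L, geo$exon1_len - 1L)
    e2_start <- geo$exon1_len + geo$intron_len
    e2 <- c(e2_start, g$gene_len - 1L)
    cds2 <- c(e2_start, e2_start + geo$cds2_len - 1L)
    utr <- c(e2_start + geo$cds2_len, g$gene_len - 1L)
    seg <- function(type, off) {
      a <- .tx2g(g$gene_start, g$gene_end, g$strand, off[1])
      b <- .tx2g(g$gene_start, g$gene_end, g$strand, off[2])
      tibble::tibble(
        chrom = g$chrom, start = min(a, b), end = max(a, b),
        strand = g$strand, type = type,
        gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".t1")
      )
    }
    dplyr::bind_rows(
      seg("gene", c(0L, g$gene_len - 1L)),
      seg("transcript", c(0L, g$gene_len - 1L)),
      seg("exon", e1), seg("exon", e2),
      seg("CDS", e1), seg("CDS", cds2),
      seg("three_prime_utr", utr)
    )
  })
}

.write_gtf <- function(anno, path) {
  lines <- sprintf(
    "%s\tapatag_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    anno$chrom, anno$type, anno$start, anno$end, anno$strand,
    anno$gene_id, anno$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Simulate cluster-labelled aligned 3' tag reads
#'
#' Each read draws a cell (hence cluster), a gene, then a pA site according to
#' that cluster's usage proportions; with probability `internal_priming_rate`
#' the read instead originates at the gene's planted A-rich decoy. The cDNA
#' fragment length is truncated-normal in `[read_length, fragment_max]` (also
#' bounded by the room available upstream of the site within its exon or
#' intron), and the read footprint covers the fragment's 5'-most `read_length`
#' bases, so the read's strand-aware 3' end lies at or upstream of the pA site.
#'
#' @inheritParams simulate_reference
#' @param reference The list returned by [simulate_reference()].
#' @param dir Optional directory; when given, `reads.sam`, `clusters.tsv`
#'   (columns `barcode`, `cluster`) and `truth_reads.tsv` are written.
#' @return A list with `reads` (tibble: `read_id, chrom, start, end, strand,
#'   barcode, cluster`, 1-based closed coordinates), `cells`, `read_truth`,
#'   and `paths` when files were written.
#' @export
simulate_reads <- function(config, reference, dir = NULL) {
  stopifnot(inherits(config, "apa_sim_config"))
  .with_seed(config$seed + 1L, {
    cells <- tibble::tibble(
      barcode = sprintf("BC%05d", seq_len(config$n_cells_per_cluster * length(config$clusters))),
      cluster = rep(config$clusters, each = config$n_cells_per_cluster)
    )
    n_per_cell <- stats::rpois(nrow(cells), config$reads_per_cell)
    cell_idx <- rep.int(seq_len(nrow(cells)), n_per_cell)
    n <- length(cell_idx)
    if (n == 0) stop("simulation produced zero reads; increase reads_per_cell", call. = FALSE)

    genes <- reference$genes
    sites <- reference$sites
    gene_idx <- sample.int(nrow(genes), n, replace = TRUE)
    cluster_idx <- match(cells$cluster[cell_idx], config$clusters)

    priming <- stats::runif(n) < config$internal_priming_rate
    intro_p <- rep_len(config$intronic_usage, length(config$clusters))[cluster_idx] *
      genes$has_intronic[gene_idx]
    intronic <- !priming & stats::runif(n) < intro_p

    # choose the UTR site for ordinary reads, per gene x cluster usage
    site_index <- integer(n)
    ord <- which(!priming & !intronic)
    for (ci in seq_along(config$clusters)) {
      for (k in sort(unique(genes$n_sites))) {
        sel <- ord[cluster_idx[ord] == ci & genes$n_sites[gene_idx[ord]] == k]
        if (length(sel) == 0) next
        p <- .usage_for(config, ci, k)
        site_index[sel] <- sample.int(k, length(sel), replace = TRUE, prob = p)
      }
    }

    site_type <- dplyr::case_when(priming ~ "decoy", intronic ~ "intron", TRUE ~ "utr")
    site_key <- paste(genes$gene_id[gene_idx], site_type,
      ifelse(site_type == "utr", site_index, 1L),
      sep = "|"
    )
    sites$key <- paste(sites$gene_id, sites$site_type, sites$site_index, sep = "|")
    si <- match(site_key, sites$key)
    stopifnot(!anyNA(si))

    pos <- sites$position[si]
    strand <- sites$strand[si]
    chrom <- sites$chrom[si]
    lf <- .rtruncnorm_int(
      n, config$fragment_mean, config$fragment_sd,
      lo = config$read_length, hi = sites$max_frag[si]
    )
    rl <- config$read_length
    start <- ifelse(strand == "+", pos - lf + 1L, pos + lf - rl)
    end <- start + rl - 1L

    reads <- tibble::tibble(
      read_id = sprintf("r%07d", seq_len(n)),
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand,
      barcode = cells$barcode[cell_idx],
      cluster = cells$cluster[cell_idx]
    )
    read_truth <- tibble::tibble(
      read_id = reads$read_id, barcode = reads$barcode, cluster = reads$cluster,
      gene_id = genes$gene_id[gene_idx],
      site_type = site_type,
      site_index = ifelse(site_type == "utr", site_index, 1L),
      position = pos, fragment_length = lf,
      three_prime_end = .three_prime_edge(reads$start, reads$end, strand),
      internal_priming = priming
    )
    out <- list(reads = reads, cells = cells, read_truth = read_truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      sam <- file.path(dir, "reads.sam")
      write_sam(reads, reference$genome, sam, read_length = rl)
      readr::write_tsv(cells, file.path(dir, "clusters.tsv"))
      readr::write_tsv(read_truth, file.path(dir, "truth_reads.tsv"))
      out$paths <- list(
        sam = sam, clusters = file.path(dir, "clusters.tsv"),
        read_truth = file.path(dir, "truth_reads.tsv")
      )
    }
    out
  })
}

#' Simulate a complete experiment in one call
#'
#' Convenience wrapper running [simulate_reference()] then [simulate_reads()].
#'
#' @inheritParams simulate_reads
#' @return A list with `reference` and the elements of [simulate_reads()].
#' @export
simulate_apa_experiment <- function(config = sim_config(), dir = NULL) {
  ref <- simulate_reference(config, dir = dir)
  rd <- simulate_reads(config, ref, dir = dir)
  c(list(reference = ref), rd)
}

#' Write aligned reads as a SAM file
#'
#' Emits header (`@HD`, `@SQ`) plus one uniquely mapped, ungapped primary
#' alignment per read, with the cell barcode in the `CB` tag. Records are
#' sorted by chromosome and position.
#'
#' @param reads Tibble with `read_id, chrom, start, end, strand, barcode`.
#' @param genome `DNAStringSet` (for `@SQ` lengths) or FASTA path.
#' @param path Output SAM path.
#' @param read_length Read length used for the CIGAR string.
#' @param barcode_tag SAM tag name for the cell barcode (default `"CB"`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path, read_length = NULL, barcode_tag = "CB") {
  genome <- load_genome(genome)
  rl <- read_length %||% (reads$end[1] - reads$start[1] + 1L)
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome))
  )
  ord <- order(match(reads$chrom, names(genome)), reads$start)
  r <- reads[ord, ]
  body <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\t%s:Z:%s",
    r$read_id, ifelse(r$strand == "+", 0L, 16L), r$chrom, r$start,
    rl, barcode_tag, r$barcode
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

# integer truncated-normal draw via inverse CDF; vectorised over hi
.rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  fa <- stats::pnorm(lo - 0.5, mean, sd)
  fb <- stats::pnorm(hi + 0.5, mean, sd)
  u <- stats::runif(n)
  x <- round(stats::qnorm(fa + u * (fb - fa), mean, sd))
  as.integer(pmin(pmax(x, lo), hi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
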