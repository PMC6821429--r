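# Brute-force oracles, kept independent of the package implementation.

# per-base set union of 1-based closed intervals -> tibble of merged intervals
oracle_union <- function(starts, ends, max_pos = 100000L) {
  covered <- logical(max_pos)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  pos <- cumsum(r$lengths)
  begin <- pos - r$lengths + 1L
  tibble::tibble(start = begin[r$values], end = pos[r$values])
}

# per-base subtraction a \ b of closed-interval sets
oracle_subtract <- function(a_start, a_end, b_start, b_end, max_pos = 100000L) {
  covered <- logical(max_pos)
  for (i in seq_along(a_start)) covered[a_start[i]:a_end[i]] <- TRUE
  for (i in seq_along(b_start)) covered[b_start[i]:b_end[i]] <- FALSE
  r <- rle(covered)
  pos <- cumsum(r$lengths)
  begin <- pos - r$lengths + 1L
  tibble::tibble(start = begin[r$values], end = pos[r$values])
}

# per-base coverage peak caller: maximal runs with coverage >= 1, gaps <=
# max_gap merged, then intervals with < min_reads overlapping reads dropped
oracle_call_peaks <- function(starts, ends, min_reads = 1L, max_gap = 0L,
                              max_pos = 100000L) {
  cov <- integer(max_pos)
  for (i in seq_along(starts)) {
    cov[starts[i]:ends[i]] <- cov[starts[i]:ends[i]] + 1L
  }
  covered <- cov >= 1L
  # merge uncovered gaps of length <= max_gap between covered runs
  if (max_gap > 0) {
    r <- rle(covered)
    pos <- cumsum(r$lengths)
    begin <- pos - r$lengths + 1L
    inner <- which(!r$values & r$lengths <= max_gap &
      seq_along(r$values) > 1 & seq_along(r$values) < length(r$values))
    for (j in inner) covered[begin[j]:pos[j]] <- TRUE
  }
  r <- rle(covered)
  pos <- cumsum(r$lengths)
  begin <- pos - r$lengths + 1L
  peaks <- tibble::tibble(start = begin[r$values], end = pos[r$values])
  if (nrow(peaks) == 0) {
    return(peaks)
  }
  peaks$n_reads <- vapply(seq_len(nrow(peaks)), function(i) {
    sum(starts <= peaks$end[i] & ends >= peaks$start[i])
  }, integer(1))
  peaks[peaks$n_reads >= min_reads, , drop = FALSE]
}

# Pearson chi-squared on a contingency matrix from first principles
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up from first principles
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# proximal PUI straight from the formula, geometric mean via prod()
oracle_proximal_pui <- function(counts) {
  x <- counts + 1
  log2(x[1] / prod(x)^(1 / length(x)))
}

# upper-tail binomial probability by direct summation
oracle_binom_upper <- function(k, n) {
  sum(vapply(k:n, function(i) choose(n, i) * 0.5^n, numeric(1)))
}

# A-run detection by run-length scan (no regex)
oracle_has_a_run <- function(seq, len) {
  bases <- strsplit(seq, "")[[1]]
  if (length(bases) == 0) {
    return(FALSE)
  }
  r <- rle(bases == "A")
  any(r$values & r$lengths >= len)
}

# quantile normalisation with tie-averaged target values
oracle_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "average")
    out[, j] <- vapply(rk, function(r) {
      lo <- floor(r)
      hi <- ceiling(r)
      mean(target[c(lo, hi)])
    }, numeric(1))
  }
  out
}
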