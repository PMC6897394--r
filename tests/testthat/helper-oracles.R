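suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## shorthand: GRanges from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}

## random interval set on short chromosomes (0-based half-open)
random_intervals <- function(n, chroms = c("c1", "c2"), chrom_len = 10000L,
                            max_width = 400L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start0 <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  gr0(chrom, start0, start0 + width)
}

## per-base brute-force merge oracle: paint bases, close gaps <= gap between
## consecutive covered runs, return the resulting blocks (0-based half-open)
oracle_merge <- function(gr, gap, chrom_len = 20000L) {
  out <- NULL
  for (ch in sort(unique(as.character(seqnames(gr))))) {
    g <- gr[as.character(seqnames(gr)) == ch]
    covered <- logical(chrom_len)
    for (i in seq_along(g)) {
      covered[start(g)[i]:end(g)[i]] <- TRUE  # 1-based base indices
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ## close internal uncovered runs of length <= gap
    for (j in which(!r$values)) {
      if (j > 1L && j < length(r$values) && r$lengths[j] <= gap) {
        covered[starts[j]:ends[j]] <- TRUE
      }
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      out <- rbind(out, data.frame(chrom = ch, start0 = starts[keep] - 1L,
                                   end0 = ends[keep]))
    }
  }
  out[order(out$chrom, out$start0), , drop = FALSE]
}

## per-base brute-force overlap oracle (min_overlap = 1)
oracle_overlaps <- function(a, b, chrom_len = 20000L) {
  cov <- list()
  for (ch in unique(as.character(seqnames(b)))) {
    v <- logical(chrom_len)
    g <- b[as.character(seqnames(b)) == ch]
    for (i in seq_along(g)) v[start(g)[i]:end(g)[i]] <- TRUE
    cov[[ch]] <- v
  }
  vapply(seq_along(a), function(i) {
    ch <- as.character(seqnames(a))[i]
    if (is.null(cov[[ch]])) return(FALSE)
    any(cov[[ch]][start(a)[i]:end(a)[i]])
  }, logical(1L))
}

## independent rank-scan oracle for the ranked-ordering cutoff: explicit
## pointwise loop over the scaled curve, first segment with slope > 1
oracle_tangent <- function(scores) {
  n <- length(scores)
  smax <- max(scores)
  if (smax <= 0) return(list(cutoff_score = smax, cutoff_rank = NA_integer_))
  for (i in 1:(n - 1L)) {
    x1 <- i / n; x2 <- (i + 1) / n
    y1 <- scores[i] / smax; y2 <- scores[i + 1] / smax
    if ((y2 - y1) / (x2 - x1) > 1) {
      return(list(cutoff_score = scores[i], cutoff_rank = i))
    }
  }
  list(cutoff_score = scores[n], cutoff_rank = NA_integer_)
}

## exact two-sided binomial p by direct tail summation over the mass function
oracle_binom_two_sided <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}
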