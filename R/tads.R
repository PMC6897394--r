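## TAD calling from a binned intra-chromosomal contact matrix (simplified
## diamond-statistic caller in the TopDom style) and permutation enrichment
## of features at TAD boundaries.

#' Construct a contact matrix
#'
#' @param mat square numeric matrix of binned contact counts; bin i (0-based)
#'   covers `[i * bin_size, (i + 1) * bin_size)`.
#' @param bin_size bin width in bp (default 40 kb).
#' @param chrom chromosome name.
#' @return a `ContactMatrix`.
#' @export
contact_matrix <- function(mat, bin_size = 40000L, chrom = "chr1") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  if (any(!is.finite(mat))) stop("contact matrix must be finite")
  if (any(mat < 0)) stop("contact matrix must be non-negative")
  if (max(abs(mat - t(mat))) > 1e-6) stop("contact matrix not symmetric (tolerance 1e-6)")
  mat <- (mat + t(mat)) / 2
  dimnames(mat) <- NULL
  structure(list(chrom = chrom, bin_size = as.integer(bin_size), matrix = mat),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat("ContactMatrix:", x$chrom, nrow(x$matrix), "bins of", x$bin_size, "bp\n")
  invisible(x)
}

#' Read a contact matrix from text
#'
#' Dense: whitespace/tab-separated n x n numeric table. Sparse: triplet
#' lines `bin_i bin_j value` with 0-based bin indices; triplets are
#' mirrored across the diagonal and missing cells are 0.
#'
#' @param path file path.
#' @param format `"dense"` or `"sparse"`.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @param n_bins matrix dimension for sparse input (default: max index + 1).
#' @return a `ContactMatrix`.
#' @export
read_contact_matrix <- function(path, format = c("dense", "sparse"),
                                bin_size = 40000L, chrom = "chr1",
                                n_bins = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    mat <- as.matrix(utils::read.table(path, header = FALSE))
  } else {
    tri <- utils::read.table(path, header = FALSE,
                             col.names = c("i", "j", "value"))
    if (any(tri$i < 0 | tri$j < 0)) stop("sparse bin indices must be >= 0")
    if (any(tri$value < 0)) stop("contact values must be non-negative")
    n <- if (is.null(n_bins)) max(tri$i, tri$j) + 1L else as.integer(n_bins)
    mat <- matrix(0, n, n)
    mat[cbind(tri$i + 1L, tri$j + 1L)] <- tri$value
    mat[cbind(tri$j + 1L, tri$i + 1L)] <- tri$value
  }
  contact_matrix(mat, bin_size = bin_size, chrom = chrom)
}

diamond_cells <- function(mat, g, w) {
  n <- nrow(mat)
  rows <- max(1L, g - w + 1L):g
  cols <- (g + 1L):min(n, g + w)
  as.numeric(mat[rows, cols, drop = FALSE])
}

#' Diamond bin-signal along a contact matrix
#'
#' For each inter-bin gap g (between bins g and g+1, 1-based; there are
#' n - 1 gaps) the statistic is the mean of the w x w upstream-vs-downstream
#' diamond submatrix, clipped at the matrix edges. Low values mark candidate
#' domain boundaries.
#'
#' @param cm a `ContactMatrix`.
#' @param w diamond half-width in bins.
#' @return numeric vector of length n - 1.
#' @export
bin_signal <- function(cm, w = 5L) {
  stopifnot(inherits(cm, "ContactMatrix"))
  n <- nrow(cm$matrix)
  if (n <= 2L) stop("need more than 2 bins")
  if (w < 1L) stop("w must be >= 1")
  vapply(seq_len(n - 1L), function(g) mean(diamond_cells(cm$matrix, g, w)),
         numeric(1L))
}

#' Call TADs from a contact matrix
#'
#' Candidate boundaries are strict local minima of [bin_signal()]; each is
#' kept only if its diamond cells are significantly lower than the pooled
#' diamond cells of the `w` flanking gaps on each side (one-sided Wilcoxon
#' rank-sum, p < `p_value_cutoff`). Domains are the maximal bin runs between
#' consecutive boundaries; runs shorter than `min_domain_bins` are absorbed
#' across their weaker junction (the flanking boundary with the larger
#' bin-signal, i.e. the shallower minimum, is dropped). A constant matrix
#' yields a single domain and no boundaries.
#'
#' Boundary bins are reported as 0-based indices of the first bin of the
#' downstream domain; each boundary region is that bin extended by `flank`
#' bp on both sides.
#'
#' @param cm a `ContactMatrix`.
#' @param w diamond half-width in bins (default 5).
#' @param min_domain_bins minimum domain length in bins.
#' @param p_value_cutoff significance filter for candidate minima.
#' @param flank bp added on each side of a boundary bin (default 20 kb).
#' @return a `TADSet`: list with `domains` (`GRanges`), `boundary_bins`
#'   (0-based), `boundary_regions` (`GRanges`), `bin_signal`, `n_bins`,
#'   `bin_size`, `chrom`, `flank`.
#' @export
call_tads <- function(cm, w = 5L, min_domain_bins = 2L,
                      p_value_cutoff = 0.05, flank = 20000L) {
  stopifnot(inherits(cm, "ContactMatrix"))
  bs <- bin_signal(cm, w)
  n <- nrow(cm$matrix)
  ngap <- n - 1L
  cand <- which(vapply(seq_len(ngap), function(g) {
    g > 1L && g < ngap && bs[g] < bs[g - 1L] && bs[g] < bs[g + 1L]
  }, logical(1L)))
  keep <- vapply(cand, function(g) {
    here <- diamond_cells(cm$matrix, g, w)
    flanks <- setdiff(intersect((g - w):(g + w), seq_len(ngap)), g)
    pooled <- unlist(lapply(flanks, function(f) diamond_cells(cm$matrix, f, w)))
    p <- suppressWarnings(stats::wilcox.test(here, pooled,
                                             alternative = "less")$p.value)
    is.finite(p) && p < p_value_cutoff
  }, logical(1L))
  bounds <- cand[keep]  # gap index g = 0-based index of the downstream bin
  ## enforce the minimum domain length: drop the weaker junction of any
  ## too-short run until all runs are long enough
  repeat {
    starts <- c(0L, bounds)
    ends <- c(bounds, n)
    len <- ends - starts
    short <- which(len < min_domain_bins)
    if (length(bounds) == 0L || length(short) == 0L) break
    i <- short[which.min(len[short])]
    left <- if (i > 1L) bounds[i - 1L] else NA_integer_
    right <- if (i <= length(bounds)) bounds[i] else NA_integer_
    drop_bound <- if (is.na(left)) right
                  else if (is.na(right)) left
                  else if (bs[left] >= bs[right]) left else right
    bounds <- setdiff(bounds, drop_bound)
  }
  starts <- c(0L, bounds)
  ends <- c(bounds, n)
  domains <- bed0_to_granges(cm$chrom, starts * cm$bin_size, ends * cm$bin_size)
  S4Vectors::mcols(domains)$n_bins <- ends - starts
  boundary_regions <- boundary_flank_regions(bounds, n, cm$bin_size, cm$chrom, flank)
  structure(list(domains = domains, boundary_bins = bounds,
                 boundary_regions = boundary_regions, bin_signal = bs,
                 n_bins = n, bin_size = cm$bin_size, chrom = cm$chrom,
                 flank = as.integer(flank)),
            class = "TADSet")
}

boundary_flank_regions <- function(bins0, n, bin_size, chrom, flank) {
  if (length(bins0) == 0L) {
    return(GenomicRanges::GRanges())
  }
  start0 <- pmax(0, bins0 * bin_size - flank)
  end0 <- pmin(n * bin_size, (bins0 + 1) * bin_size + flank)
  bed0_to_granges(chrom, start0, end0)
}

#' @export
print.TADSet <- function(x, ...) {
  cat("TADSet:", length(x$domains), "domains,", length(x$boundary_bins),
      "boundaries on", x$chrom, "(", x$n_bins, "bins of", x$bin_size, "bp )\n")
  invisible(x)
}

#' Permutation enrichment of features at TAD boundaries
#'
#' The observed statistic is the number of features overlapping any
#' boundary region (boundary bin extended by `flank` bp each side). Each
#' permutation draws, without replacement, the same number of bins uniformly
#' from all matrix bins (`n_bins_drawn = "auto"`; or a user-supplied count),
#' builds equivalently flanked regions, and recounts. The empirical p-value
#' uses the add-one rule `(1 + #(perm >= obs)) / (n_perm + 1)`, so it is
#' never zero; the z-score is `(obs - mean) / sd` of the permutation null.
#' Fully reproducible given `seed`.
#'
#' @param features `GRanges` of features (e.g. CTCF sites, broad domains,
#'   super-enhancers).
#' @param tads a `TADSet` with at least one boundary.
#' @param flank bp each side of a bin (default 20 kb).
#' @param n_perm number of permutations (default 1000).
#' @param n_bins_drawn `"auto"` (number of boundary bins) or an integer.
#' @param seed RNG seed.
#' @return an `EnrichmentResult`: list with `observed`, `expected_mean`,
#'   `expected_sd`, `z_score`, `empirical_p`, `n_perm`, `n_bins_drawn`,
#'   `seed`, `perm_counts`.
#' @export
boundary_enrichment <- function(features, tads, flank = 20000L,
                                n_perm = 1000L, n_bins_drawn = "auto",
                                seed = 1L) {
  stopifnot(inherits(tads, "TADSet"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(tads$boundary_bins) == 0L) {
    stop("TADSet has no boundaries; run call_tads() first")
  }
  k <- if (identical(n_bins_drawn, "auto")) length(tads$boundary_bins)
       else as.integer(n_bins_drawn)
  if (k < 1L || k > tads$n_bins) stop("n_bins_drawn out of range")
  feats <- features[as.character(GenomicRanges::seqnames(features)) == tads$chrom]
  n <- tads$n_bins
  bsz <- tads$bin_size
  ## feature f overlaps the flanked region of bin b iff b is in a contiguous
  ## index range; precompute that range once per feature
  fs0 <- GenomicRanges::start(feats) - 1L
  fe0 <- GenomicRanges::end(feats)
  ## bin b's flanked region is [b*bsz - flank, (b+1)*bsz + flank): overlap
  ## with a feature [fs0, fe0) iff b > (fs0 - flank)/bsz - 1 and
  ## b < (fe0 + flank)/bsz
  lo <- pmax(0L, as.integer(floor((fs0 - flank) / bsz - 1)) + 1L)
  hi <- pmin(n - 1L, as.integer(ceiling((fe0 + flank) / bsz)) - 1L)
  valid <- lo <= hi
  lo <- lo[valid]; hi <- hi[valid]
  count_hits <- function(bins0) {
    ind <- integer(n + 1L)
    ind[bins0 + 1L] <- 1L
    cs <- c(0L, cumsum(ind))
    sum(cs[hi + 2L] - cs[lo + 1L] > 0L)
  }
  observed <- count_hits(tads$boundary_bins)
  perm_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      count_hits(sample.int(n, k) - 1L)
    }, numeric(1L))
  })
  mu <- mean(perm_counts)
  sdv <- stats::sd(perm_counts)
  structure(list(
    observed = observed, expected_mean = mu, expected_sd = sdv,
    z_score = if (isTRUE(sdv > 0)) (observed - mu) / sdv else NA_real_,
    empirical_p = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
    n_perm = as.integer(n_perm), n_bins_drawn = k, seed = as.integer(seed),
    perm_counts = perm_counts
  ), class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: observed %d vs expected %.2f (sd %.2f), z = %.2f, empirical p = %.4g (%d permutations of %d bins, seed %d)\n",
    x$observed, x$expected_mean, x$expected_sd,
    ifelse(is.na(x$z_score), NaN, x$z_score), x$empirical_p, x$n_perm,
    x$n_bins_drawn, x$seed))
  invisible(x)
}

## evaluate expr under a local RNG state seeded with `seed`, restoring the
## caller's state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
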