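## Differential enrichment of consensus regions between treated and control
## ChIP-seq samples, genomic-location annotation, gene assignment within a
## distance window, and expression comparison by domain category.

#' Build a gene model
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` giving the gene body in 0-based half-open coordinates.
#' @return a `GeneModel`: list with `genes` (`GRanges` of gene bodies, with
#'   `gene_id`) and `tss` (width-1 `GRanges`, strand-aware: body start for
#'   `+`, last base for `-`).
#' @export
gene_model <- function(df) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df))) stop("gene model needs columns: ", paste(need, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(df$end <= df$start)) stop("gene end must exceed start")
  genes <- bed0_to_granges(df$chrom, df$start, df$end,
                           strand = df$strand, gene_id = df$gene_id)
  tss <- GenomicRanges::resize(genes, width = 1L, fix = "start")
  structure(list(genes = genes, tss = tss), class = "GeneModel")
}

#' Read a gene model from TSV
#'
#' Tab-separated with header `gene_id chrom strand start end` (0-based
#' half-open gene body).
#'
#' @param path file path.
#' @return a `GeneModel`.
#' @export
read_gene_model <- function(path) {
  gene_model(utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

#' Count fragments or signal in consensus regions
#'
#' With fragment intervals per sample, a fragment is assigned to a region
#' when its midpoint falls inside it (half-open; a midpoint exactly at the
#' region end is outside). With signal tracks (a `score` column present),
#' the rounded signal area per region is used instead.
#'
#' @param regions consensus `GRanges`.
#' @param samples named list of `GRanges`: fragments, or tracks with `score`.
#' @param condition named character vector mapping each sample to
#'   `"treated"` or `"control"`.
#' @return a `RegionCounts`: list with `regions`, integer matrix `counts`
#'   (region x sample), `condition`, `library_size` (column sums).
#' @export
count_in_regions <- function(regions, samples, condition) {
  if (is.null(names(samples))) stop("samples must be named")
  condition <- condition[names(samples)]
  if (!all(condition %in% c("treated", "control"))) {
    stop("condition must be 'treated' or 'control'")
  }
  if (!all(c("treated", "control") %in% condition)) {
    stop("need at least one treated and one control sample")
  }
  counts <- vapply(samples, function(s) {
    if ("score" %in% names(S4Vectors::mcols(s))) {
      as.integer(round(region_signal(s, regions, mode = "area")))
    } else {
      ## fragment midpoint in 0-based coords, back to a 1-based point
      mid0 <- (GenomicRanges::start(s) - 1L + GenomicRanges::end(s)) %/% 2L
      pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(s),
                                    IRanges::IRanges(mid0 + 1L, width = 1L))
      GenomicRanges::countOverlaps(regions, pts)
    }
  }, integer(length(regions)))
  counts <- matrix(counts, nrow = length(regions),
                   dimnames = list(region_id(regions), names(samples)))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero total counts: ",
                          paste(names(lib)[lib == 0], collapse = ", "))
  structure(list(regions = regions, counts = counts, condition = condition,
                 library_size = lib),
            class = "RegionCounts")
}

#' Differential enrichment of regions between conditions
#'
#' Replicates are pooled per condition. For region i with pooled counts
#' (t_i, c_i), the p-value is an exact two-sided binomial test of t_i
#' successes in t_i + c_i trials at a null treated proportion p0, FDR is
#' Benjamini-Hochberg over all regions, and direction is assigned at
#' `fdr < fdr_threshold` by the sign of the fold-change. The fold-change is
#' `log2(((t+1)/(c+1)) / (p0/(1-p0)))` — pseudocount 1 in the fold-change
#' only, never in the test.
#'
#' The null proportion p0 is, by default, estimated robustly as the median
#' over regions of t_i/c_i (`"median-ratio"`), which is insensitive to a
#' minority of genuinely changed regions; `"library-size"` uses the pooled
#' totals p0 = T/(T+C) and is appropriate when changes are known to be
#' balanced or library sizes are externally calibrated.
#'
#' Swapping the condition labels negates every fold-change and leaves the
#' p-values unchanged. A region with t_i + c_i = 0 gets p = 1, log2fc = 0.
#'
#' @param rc a `RegionCounts`.
#' @param fdr_threshold FDR below which a region is called changed.
#' @param normalization `"median-ratio"` (default) or `"library-size"`.
#' @return data.frame: region coordinates (0-based half-open), `t`, `c`
#'   pooled counts, `log2fc`, `p_value`, `fdr`, `direction` (factor:
#'   increased / decreased / unchanged).
#' @export
differential_regions <- function(rc, fdr_threshold = 0.1,
                                 normalization = c("median-ratio", "library-size")) {
  stopifnot(inherits(rc, "RegionCounts"))
  normalization <- match.arg(normalization)
  tr <- rc$condition == "treated"
  t_i <- as.integer(rowSums(rc$counts[, tr, drop = FALSE]))
  c_i <- as.integer(rowSums(rc$counts[, !tr, drop = FALSE]))
  if (normalization == "median-ratio") {
    ok <- t_i > 0 & c_i > 0
    if (!any(ok)) stop("no region with counts in both conditions")
    ## median log-ratio, so that swapping the condition labels flips the
    ## estimate exactly (p0 -> 1 - p0) for any number of regions
    m <- exp(stats::median(log(t_i[ok] / c_i[ok])))
    p0 <- m / (1 + m)
  } else {
    T_tot <- sum(rc$library_size[tr])
    C_tot <- sum(rc$library_size[!tr])
    p0 <- T_tot / (T_tot + C_tot)
  }
  n_i <- t_i + c_i
  p <- vapply(seq_along(t_i), function(i) {
    if (n_i[i] == 0L) return(1)
    stats::binom.test(t_i[i], n_i[i], p = p0)$p.value
  }, numeric(1L))
  lfc <- ifelse(n_i == 0L, 0,
                log2((t_i + 1) / (c_i + 1)) - log2(p0 / (1 - p0)))
  fdr <- stats::p.adjust(p, method = "BH")
  dir <- rep("unchanged", length(t_i))
  sig <- fdr < fdr_threshold & lfc != 0
  dir[sig & lfc > 0] <- "increased"
  dir[sig & lfc < 0] <- "decreased"
  gr <- rc$regions
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    t = t_i, c = c_i, log2fc = lfc, p_value = p, fdr = fdr,
    direction = factor(dir, levels = c("increased", "decreased", "unchanged")),
    row.names = NULL
  )
}

#' Annotate regions by genomic location
#'
#' Labels each region `promoter` (overlaps a strand-aware TSS window,
#' default 2000 bp upstream to 500 bp downstream of the TSS), else
#' `intragenic` (overlaps a gene body), else `distal intergenic`. The three
#' labels partition the regions.
#'
#' @param regions `GRanges`.
#' @param genes a `GeneModel`.
#' @param promoter_upstream,promoter_downstream window around the TSS, bp.
#' @return factor along `regions`.
#' @export
annotate_location <- function(regions, genes, promoter_upstream = 2000L,
                              promoter_downstream = 500L) {
  stopifnot(inherits(genes, "GeneModel"))
  if (length(genes$genes) == 0L) stop("empty gene model")
  prom <- GenomicRanges::promoters(genes$tss, upstream = promoter_upstream,
                                   downstream = promoter_downstream)
  lab <- rep("distal intergenic", length(regions))
  lab[IRanges::overlapsAny(regions, genes$genes, ignore.strand = TRUE)] <- "intragenic"
  lab[IRanges::overlapsAny(regions, prom, ignore.strand = TRUE)] <- "promoter"
  factor(lab, levels = c("promoter", "intragenic", "distal intergenic"))
}

#' Assign genes to regions within a distance window
#'
#' Links every gene whose TSS lies within `window` bp of a region's edges
#' (distance 0 when the TSS falls inside the region). A region may link many
#' genes and a gene many regions.
#'
#' @param regions `GRanges`.
#' @param genes a `GeneModel`.
#' @param window maximum TSS distance in bp (default 100 kb).
#' @return data.frame `region_id`, `gene_id`, `distance`.
#' @export
assign_genes <- function(regions, genes, window = 100000L) {
  stopifnot(inherits(genes, "GeneModel"))
  if (window < 0) stop("window must be >= 0")
  ext <- GenomicRanges::resize(GenomicRanges::granges(regions),
                               width = GenomicRanges::width(regions) + 2L * window,
                               fix = "center")
  hits <- GenomicRanges::findOverlaps(ext, genes$tss, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ## distance() is 0 for adjacent ranges and NA on overlap, which matches the
  ## 0-based offset from the region edge to the TSS (0 when the TSS is inside)
  d <- GenomicRanges::distance(regions[q], genes$tss[s], ignore.strand = TRUE)
  d[is.na(d)] <- 0L
  keep <- d <= window
  data.frame(region_id = region_id(regions)[q[keep]],
             gene_id = S4Vectors::mcols(genes$tss)$gene_id[s[keep]],
             distance = as.integer(d[keep]))
}

#' Expression change by domain category
#'
#' Given per-category gene sets and per-gene expression log2 fold-changes
#' (treatment vs control), returns each category's fold-change vector and
#' Welch's unequal-variance t-test (two-sided) for every pair of categories.
#' Categories with fewer than 2 genes are dropped with a warning. When both
#' groups are constant and equal the test is degenerate and p = 1 (t = 0);
#' constant but different groups give p = 0.
#'
#' @param category_genes named list of character vectors of gene ids.
#' @param expr_log2fc named numeric vector: gene id -> log2 fold-change.
#' @return list with `values` (named list of numeric vectors) and `tests`
#'   (data.frame `category_a`, `category_b`, `t`, `df`, `p_value`).
#' @export
expression_change_by_category <- function(category_genes, expr_log2fc) {
  vals <- lapply(category_genes, function(g) {
    v <- expr_log2fc[intersect(g, names(expr_log2fc))]
    as.numeric(v)
  })
  small <- lengths(vals) < 2L
  if (any(small)) {
    warning("categories excluded (<2 genes): ",
            paste(names(vals)[small], collapse = ", "))
    vals <- vals[!small]
  }
  cats <- names(vals)
  tests <- NULL
  if (length(cats) >= 2L) {
    pairs <- utils::combn(cats, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- vals[[pairs[1L, j]]]; b <- vals[[pairs[2L, j]]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        tt <- list(statistic = if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b)),
                   parameter = NA_real_,
                   p.value = if (mean(a) == mean(b)) 1 else 0)
      } else {
        tt <- stats::t.test(a, b, var.equal = FALSE)
      }
      data.frame(category_a = pairs[1L, j], category_b = pairs[2L, j],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
    }))
  }
  list(values = vals, tests = tests)
}
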