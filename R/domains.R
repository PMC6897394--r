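## Super-enhancer calling by ranked ordering of stitched H3K27ac regions
## (ROSE-style) and broad H3K4me3 domain calling by width percentile.

#' Stitch enhancer peaks into candidate regions
#'
#' Merges peaks whose gaps are at most `stitch_gap` bp. If a TSS set is
#' supplied, peaks falling entirely inside `TSS +/- tss_flank` are removed
#' before stitching (promoter-proximal exclusion, off by default).
#'
#' @param peaks `GRanges` of called peaks.
#' @param stitch_gap stitching window in bp. Default 12500; 5000 is the other
#'   window in common use for this analysis and is available here directly.
#' @param tss optional `GRanges` of width-1 TSS positions.
#' @param tss_flank bp on each side of a TSS defining the exclusion zone.
#' @return merged `GRanges` with `n_constituents`.
#' @export
stitch <- function(peaks, stitch_gap = 12500L, tss = NULL, tss_flank = 2500L) {
  if (length(peaks) == 0L) stop("no peaks to stitch")
  if (!is.null(tss)) {
    zones <- GenomicRanges::resize(tss, width = 2L * tss_flank + 1L, fix = "center")
    inside <- IRanges::overlapsAny(peaks, zones, type = "within")
    peaks <- peaks[!inside]
    if (length(peaks) == 0L) {
      warning("all peaks fall within TSS exclusion zones; empty result")
      return(merge_within(peaks, stitch_gap))
    }
  }
  merge_within(peaks, stitch_gap)
}

#' Score stitched regions by input-corrected signal
#'
#' Region score is the treatment signal area minus the input-control area,
#' clipped at 0; without a control the treatment area is the score. Ranks are
#' 1..n by ascending score (ties broken by coordinate).
#'
#' @param stitched merged `GRanges` (from [stitch()]).
#' @param treat treatment `GRanges` signal track (with `score`).
#' @param ctrl optional input-control track.
#' @return `GRanges` sorted by coordinate with metadata `score` and `rank`.
#' @export
score_regions <- function(stitched, treat, ctrl = NULL) {
  regions <- sort(stitched)
  s <- region_signal(treat, regions, mode = "area")
  if (!is.null(ctrl)) s <- s - region_signal(ctrl, regions, mode = "area")
  s <- pmax(s, 0)
  S4Vectors::mcols(regions)$score <- s
  S4Vectors::mcols(regions)$rank <- rank_ascending(s)
  regions
}

## rank 1..n ascending in score; ties resolved by position in the
## coordinate-sorted input so output is deterministic
rank_ascending <- function(s) {
  ord <- order(s, seq_along(s))
  r <- integer(length(s))
  r[ord] <- seq_along(s)
  r
}

#' Ranked-ordering cutoff for super-enhancer calling
#'
#' Both axes of the ranked score curve are scaled to `[0, 1]`
#' (`x = rank/n`, `y = score/max(score)`) and the discrete slope between
#' consecutive points is scanned from the low-score end; the cutoff is the
#' unscaled score at the lower end of the first segment whose slope exceeds 1.
#' Regions scoring strictly above the cutoff are super-enhancers. The cutoff
#' is invariant under positive rescaling of the scores.
#'
#' If the curve never reaches slope 1 (e.g. all scores equal), the cutoff is
#' the maximum score, no region is called super, and a warning is raised.
#'
#' @param scores numeric vector of region scores, sorted ascending.
#' @return list with `cutoff_score` and `cutoff_rank` (the rank at the
#'   cutoff; `NA` when no crossing exists).
#' @export
tangent_cutoff <- function(scores) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scores")
  if (is.unsorted(scores)) stop("scores must be sorted ascending")
  smax <- scores[n]
  if (smax <= 0) {
    warning("all scores are zero; no super-enhancers")
    return(list(cutoff_score = smax, cutoff_rank = NA_integer_))
  }
  ## slope of the scaled curve between ranks i and i+1: (dy/smax) / (1/n)
  slopes <- n * diff(scores) / smax
  i <- which(slopes > 1)
  if (length(i) == 0L) {
    warning("ranked curve never exceeds slope 1; no super-enhancers")
    return(list(cutoff_score = smax, cutoff_rank = NA_integer_))
  }
  list(cutoff_score = scores[i[1L]], cutoff_rank = i[1L])
}

#' Call super-enhancers from peaks and signal
#'
#' Composition of [stitch()], [score_regions()] and [tangent_cutoff()]:
#' stitched regions are scored against input and ranked, the ranked-curve
#' cutoff is computed, and regions scoring strictly above it are flagged
#' super-enhancers.
#'
#' @inheritParams stitch
#' @inheritParams score_regions
#' @return a `RankedRegionSet`: list with `regions` (`GRanges` with `score`,
#'   `rank`, `is_super`), `cutoff_score`, `cutoff_rank`.
#' @export
call_super_enhancers <- function(peaks, treat, ctrl = NULL,
                                 stitch_gap = 12500L, tss = NULL,
                                 tss_flank = 2500L) {
  if (length(peaks) == 0L) {
    warning("empty peak set; empty result")
    regions <- GenomicRanges::GRanges()
    S4Vectors::mcols(regions)$score <- numeric()
    S4Vectors::mcols(regions)$rank <- integer()
    S4Vectors::mcols(regions)$is_super <- logical()
    return(structure(list(regions = regions, cutoff_score = NA_real_,
                          cutoff_rank = NA_integer_),
                     class = "RankedRegionSet"))
  }
  stitched <- stitch(peaks, stitch_gap = stitch_gap, tss = tss, tss_flank = tss_flank)
  scored <- score_regions(stitched, treat, ctrl)
  s <- S4Vectors::mcols(scored)$score
  cut <- tangent_cutoff(sort(s))
  S4Vectors::mcols(scored)$is_super <- s > cut$cutoff_score
  structure(list(regions = scored, cutoff_score = cut$cutoff_score,
                 cutoff_rank = cut$cutoff_rank),
            class = "RankedRegionSet")
}

#' @export
print.RankedRegionSet <- function(x, ...) {
  cat("RankedRegionSet:", length(x$regions), "regions,",
      sum(S4Vectors::mcols(x$regions)$is_super), "super-enhancers",
      sprintf("(cutoff score %.4g)\n", x$cutoff_score))
  invisible(x)
}

#' Ranked-region table
#'
#' @param x a `RankedRegionSet`.
#' @return data.frame with region coordinates (0-based half-open), score,
#'   rank and super flag, ordered by descending rank.
#' @export
ranked_table <- function(x) {
  stopifnot(inherits(x, "RankedRegionSet"))
  gr <- x$regions
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = S4Vectors::mcols(gr)$score,
    rank = S4Vectors::mcols(gr)$rank,
    is_super = S4Vectors::mcols(gr)$is_super
  )
  df[order(-df$rank), , drop = FALSE]
}

#' Call broad domains by width percentile
#'
#' Peaks are ranked by width descending (ties broken by chromosome then
#' start, ascending) and exactly `ceiling(top_fraction * n)` are kept as
#' broad domains; the width threshold is the width of the last kept peak.
#'
#' @param peaks `GRanges` of peaks.
#' @param top_fraction fraction of peaks to keep, in (0, 1). Default 0.05
#'   (the "top 5% by domain size" rule for broad H3K4me3 domains).
#' @return a `BroadDomainSet`: list with `domains` (`GRanges`, coordinate
#'   sorted), `width_threshold`, `top_fraction`, `n_input`.
#' @export
call_broad_domains <- function(peaks, top_fraction = 0.05) {
  if (length(peaks) == 0L) stop("empty peak set")
  if (top_fraction <= 0 || top_fraction >= 1) stop("top_fraction must be in (0, 1)")
  n <- length(peaks)
  k <- as.integer(ceiling(top_fraction * n))
  if (top_fraction * n < 1) warning("top_fraction * n < 1; keeping a single peak")
  ord <- order(-GenomicRanges::width(peaks),
               as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks))
  kept <- peaks[ord[seq_len(k)]]
  structure(list(domains = sort(kept),
                 width_threshold = GenomicRanges::width(peaks)[ord[k]],
                 top_fraction = top_fraction, n_input = n),
            class = "BroadDomainSet")
}

#' @export
print.BroadDomainSet <- function(x, ...) {
  cat("BroadDomainSet:", length(x$domains), "of", x$n_input,
      "peaks kept (width threshold", x$width_threshold, "bp)\n")
  invisible(x)
}
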