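#' @importFrom GenomicRanges GRanges reduce findOverlaps countOverlaps start end width strand seqnames promoters resize
#' @importFrom IRanges IRanges overlapsAny pintersect subsetByOverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb sortSeqlevels seqlevels
#' @importFrom stats rnorm rpois runif median sd p.adjust binom.test t.test wilcox.test ks.test setNames
#' @importFrom utils write.table read.table packageVersion
NULL

## All coordinates on disk are BED-style 0-based half-open; in memory every
## region lives in a GRanges (1-based closed).  Conversion happens only here.

bed0_to_granges <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), ...)
}

#' Read a BED-family peak file
#'
#' Reads BED3+/narrowPeak/broadPeak into a `GRanges`. Coordinates are 0-based
#' half-open on disk and become the usual 1-based closed `GRanges` in memory.
#' For narrowPeak/broadPeak the `signalValue` column is mapped to the `score`
#' metadata column. File order is preserved; `sort()` gives the sorted view.
#'
#' `track`/`browser` lines are skipped with a warning. A malformed line
#' (fewer than 3 fields, non-integer coordinates, `end <= start`, negative
#' start) raises an error naming the line number. An empty file yields an
#' empty `GRanges`.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"bed"`, `"narrowPeak"`,
#'   `"broadPeak"`.
#' @return `GRanges` with metadata columns `name` and `score`.
#' @export
read_bed <- function(path, format = c("auto", "bed", "narrowPeak", "broadPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.narrowPeak$", path)) "narrowPeak"
              else if (grepl("\\.broadPeak$", path)) "broadPeak" else "bed"
  }
  lines <- readLines(path)
  skip <- grepl("^(track|browser)([[:space:]]|$)", lines)
  if (any(skip)) {
    warning(sum(skip), " track/browser line(s) skipped in ", path)
  }
  keep <- which(!skip & nzchar(lines))
  if (length(keep) == 0L) return(GenomicRanges::GRanges(name = character(), score = numeric()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", keep[which(nf < 3L)[1L]], ": fewer than 3 tab-separated columns in ", path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0L | end0 <= start0 | !nzchar(chrom)
  if (any(bad)) {
    stop("line ", keep[which(bad)[1L]], ": invalid interval (need integer start >= 0, end > start) in ", path)
  }
  get_col <- function(i, default) {
    ifelse(nf >= i, vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, ""), default)
  }
  name <- get_col(4L, ".")
  strand <- get_col(6L, "*")
  strand[!strand %in% c("+", "-")] <- "*"
  score <- if (format %in% c("narrowPeak", "broadPeak")) {
    suppressWarnings(as.numeric(get_col(7L, "0")))
  } else {
    suppressWarnings(as.numeric(get_col(5L, "0")))
  }
  score[is.na(score)] <- 0
  bed0_to_granges(chrom, start0, end0, strand = strand, name = name, score = score)
}

#' Write regions as BED6
#'
#' Writes 0-based half-open BED6 (`chrom start end name score strand`);
#' `read_bed(write_bed(x))` reproduces coordinates exactly. Unstranded
#' ranges get strand `"."`, a missing name `"."`, a missing score `0`.
#'
#' @param regions a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  mc <- S4Vectors::mcols(regions)
  name <- if ("name" %in% names(mc)) as.character(mc$name) else rep(".", length(regions))
  score <- if ("score" %in% names(mc)) as.numeric(mc$score) else rep(0, length(regions))
  strand <- as.character(GenomicRanges::strand(regions))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = name, score = score, strand = strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Four tab-separated columns (`chrom start end value`), 0-based half-open.
#' Values must be finite and non-negative; intervals must be disjoint within
#' each chromosome. `track`/`browser` lines are skipped with a warning.
#'
#' @param path file path.
#' @return `GRanges` with numeric `score` metadata column, sorted.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  skip <- grepl("^(track|browser)([[:space:]]|$)", lines)
  if (any(skip)) warning(sum(skip), " track/browser line(s) skipped in ", path)
  keep <- which(!skip & nzchar(lines))
  if (length(keep) == 0L) return(GenomicRanges::GRanges(score = numeric()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("line ", keep[which(lengths(fields) < 4L)[1L]], ": bedGraph needs 4 columns in ", path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0L | end0 <= start0
  if (any(bad)) stop("line ", keep[which(bad)[1L]], ": invalid interval in ", path)
  if (any(!is.finite(value) | value < 0)) {
    stop("line ", keep[which(!is.finite(value) | value < 0)[1L]],
         ": signal values must be finite and >= 0 in ", path)
  }
  gr <- sort(bed0_to_granges(chrom, start0, end0, score = value))
  validate_track(gr)
  gr
}

#' Write a signal track as bedGraph
#'
#' @param track `GRanges` with a numeric `score` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    value = as.numeric(S4Vectors::mcols(track)$score)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_track <- function(track) {
  if (length(track) == 0L) return(invisible(track))
  v <- S4Vectors::mcols(track)$score
  if (is.null(v)) stop("signal track needs a 'score' metadata column")
  if (any(!is.finite(v) | v < 0)) stop("signal track values must be finite and >= 0")
  cov <- GenomicRanges::reduce(track, min.gapwidth = 0L)
  if (sum(GenomicRanges::width(cov)) != sum(GenomicRanges::width(track))) {
    stop("signal track intervals must be disjoint within each chromosome")
  }
  invisible(track)
}

#' Merge intervals separated by at most a gap
#'
#' Two same-chromosome intervals are joined when the gap between them is at
#' most `gap` bp (bookended intervals merge at `gap = 0`); joining is
#' transitive. Output is disjoint, sorted, and records the number of
#' constituent input intervals per merged region (`n_constituents`).
#'
#' @param regions a `GRanges`.
#' @param gap maximum gap in bp (`>= 0`).
#' @return sorted disjoint `GRanges` with `n_constituents`.
#' @export
merge_within <- function(regions, gap = 0L) {
  if (gap < 0) stop("gap must be >= 0")
  if (length(regions) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$n_constituents <- integer()
    return(out)
  }
  gr <- GenomicRanges::granges(regions)
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  merged <- GenomicRanges::reduce(sort(gr), min.gapwidth = gap + 1L,
                                  with.revmap = TRUE)
  S4Vectors::mcols(merged)$n_constituents <- lengths(S4Vectors::mcols(merged)$revmap)
  S4Vectors::mcols(merged)$revmap <- NULL
  merged
}

#' Overlap flags and pairs between two region sets
#'
#' For each region of `a`, whether some region of `b` on the same chromosome
#' shares at least `min_overlap` bases (half-open convention: bookended
#' regions do not overlap). Also returns the full pair list with the shared
#' width per pair.
#'
#' @param a,b `GRanges`.
#' @param min_overlap minimum shared bases (`>= 1`).
#' @return list with `flag` (logical over `a`) and `pairs`
#'   (data.frame `query`, `subject`, `overlap_bp`).
#' @export
region_overlaps <- function(a, b, min_overlap = 1L) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  ## chromosome names are opaque strings; sets sharing no chromosome simply
  ## have no overlaps, so the seqlevel-mismatch warning is uninformative
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(GenomicRanges::ranges(a)[q],
                                                 GenomicRanges::ranges(b)[s]))
  flag <- logical(length(a))
  flag[unique(q)] <- TRUE
  list(flag = flag, pairs = data.frame(query = q, subject = s, overlap_bp = ov))
}

#' Signal over regions from a piecewise-constant track
#'
#' `area` sums, over the track intervals intersecting each region,
#' overlap length times track value; bases not covered by the track
#' contribute 0. `mean` divides the area by the region width.
#'
#' @param track `GRanges` with `score` (disjoint intervals).
#' @param regions `GRanges` of query regions.
#' @param mode `"area"` or `"mean"`.
#' @return numeric vector along `regions`.
#' @export
region_signal <- function(track, regions, mode = c("area", "mean")) {
  mode <- match.arg(mode)
  out <- numeric(length(regions))
  if (length(track) > 0L && length(regions) > 0L) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(regions, track))
    if (length(hits) > 0L) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(regions)[q], GenomicRanges::ranges(track)[s]))
      contrib <- ov * S4Vectors::mcols(track)$score[s]
      agg <- tapply(contrib, q, sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  if (mode == "mean") out <- out / GenomicRanges::width(regions)
  out
}
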