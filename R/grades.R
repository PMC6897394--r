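## Multi-sample domain panels: union membership, common / grade-unique
## classification, and overlap of the two broad-domain types.

#' Assemble a graded sample panel
#'
#' @param domain_sets named list of `GRanges`, one per sample.
#' @param groups named character vector mapping each sample to `"High"` or
#'   `"Low"` (tumor grade of the cell line).
#' @return a `SamplePanel`.
#' @export
sample_panel <- function(domain_sets, groups) {
  if (length(domain_sets) == 0L) stop("empty panel")
  if (is.null(names(domain_sets))) stop("domain_sets must be named by sample")
  if (!all(names(domain_sets) %in% names(groups))) {
    stop("every sample needs a group label")
  }
  groups <- groups[names(domain_sets)]
  if (!all(groups %in% c("High", "Low"))) stop("groups must be 'High' or 'Low'")
  if (!all(c("High", "Low") %in% groups)) stop("need at least one sample per group")
  structure(list(sample_ids = names(domain_sets), group_of = groups,
                 domain_sets = domain_sets),
            class = "SamplePanel")
}

#' @export
print.SamplePanel <- function(x, ...) {
  cat("SamplePanel:", length(x$sample_ids), "samples (",
      sum(x$group_of == "High"), "High,", sum(x$group_of == "Low"), "Low )\n")
  invisible(x)
}

#' Binary occupancy of union regions across a panel
#'
#' Union regions are the merged concatenation of all samples' domain sets
#' (`merge_gap` 0 by default so unrelated domains are not chained);
#' `occupancy[r, s]` is 1 iff sample `s` overlaps union region `r` by at
#' least 1 bp. Every row has at least one 1 by construction.
#'
#' @param panel a `SamplePanel`.
#' @param merge_gap gap for the union merge, bp.
#' @return a `MembershipMatrix`: list with `union_regions` (`GRanges`),
#'   `occupancy` (binary matrix region x sample), `group_of`.
#' @export
build_membership <- function(panel, merge_gap = 0L) {
  stopifnot(inherits(panel, "SamplePanel"))
  all_gr <- do.call(c, lapply(unname(panel$domain_sets), GenomicRanges::granges))
  union_regions <- merge_within(all_gr, merge_gap)
  occ <- vapply(panel$domain_sets,
                function(s) as.integer(IRanges::overlapsAny(union_regions, s)),
                integer(length(union_regions)))
  occ <- matrix(occ, nrow = length(union_regions),
                dimnames = list(region_id(union_regions), panel$sample_ids))
  structure(list(union_regions = union_regions, occupancy = occ,
                 group_of = panel$group_of),
            class = "MembershipMatrix")
}

region_id <- function(gr) {
  paste0(as.character(GenomicRanges::seqnames(gr)), ":",
         GenomicRanges::start(gr) - 1L, "-", GenomicRanges::end(gr))
}

#' Classify union regions as common or grade-unique
#'
#' `common`: present in every sample. `HGU` (High-Grade unique): present in
#' at least `min_in_group` High samples and at most `max_in_other` Low
#' samples; `LGU` symmetrically. Everything else is `other`. The default
#' (`min_in_group = "all"`, `max_in_other = 0`) is the strictest reading of
#' "unique to" a group. Labels partition the regions; swapping the group
#' labels swaps HGU and LGU exactly.
#'
#' @param m a `MembershipMatrix`.
#' @param min_in_group `"all"` or an integer count.
#' @param max_in_other maximum occupancies allowed in the other group.
#' @return factor with levels `common`, `HGU`, `LGU`, `other`.
#' @export
classify_regions <- function(m, min_in_group = "all", max_in_other = 0L) {
  stopifnot(inherits(m, "MembershipMatrix"))
  high <- names(m$group_of)[m$group_of == "High"]
  low <- names(m$group_of)[m$group_of == "Low"]
  if (length(high) == 0L || length(low) == 0L) stop("need samples in both groups")
  occ <- m$occupancy
  nh <- rowSums(occ[, high, drop = FALSE])
  nl <- rowSums(occ[, low, drop = FALSE])
  kh <- if (identical(min_in_group, "all")) length(high) else min(min_in_group, length(high))
  kl <- if (identical(min_in_group, "all")) length(low) else min(min_in_group, length(low))
  lab <- rep("other", nrow(occ))
  lab[nh >= kh & nl <= max_in_other] <- "HGU"
  lab[nl >= kl & nh <= max_in_other] <- "LGU"
  lab[nh == length(high) & nl == length(low)] <- "common"
  factor(lab, levels = c("common", "HGU", "LGU", "other"))
}

#' Overlap of the two broad-domain types by grade category
#'
#' For each grade category, regions of one domain type (e.g. broad H3K4me3,
#' "B") are flagged by >= 1 bp overlap with same-category regions of the
#' other type (super-enhancers, "S"), yielding per-category counts of
#' B-only, S-only and overlapping (B intersect S) regions.
#'
#' @param se_regions,broad_regions `GRanges` of classified union regions.
#' @param se_labels,broad_labels factors from [classify_regions()].
#' @param categories categories to compare.
#' @return named list per category: list with counts `n_b`, `n_s`,
#'   `n_b_overlap`, `n_s_overlap`, `n_b_only`, `n_s_only` and the
#'   corresponding `GRanges` subsets.
#' @export
overlap_domain_types <- function(se_regions, se_labels, broad_regions, broad_labels,
                                 categories = c("common", "HGU", "LGU")) {
  stopifnot(length(se_regions) == length(se_labels),
            length(broad_regions) == length(broad_labels))
  out <- lapply(categories, function(cat) {
    s <- se_regions[se_labels == cat]
    b <- broad_regions[broad_labels == cat]
    b_hit <- if (length(s)) IRanges::overlapsAny(b, s) else logical(length(b))
    s_hit <- if (length(b)) IRanges::overlapsAny(s, b) else logical(length(s))
    list(n_b = length(b), n_s = length(s),
         n_b_overlap = sum(b_hit), n_s_overlap = sum(s_hit),
         n_b_only = sum(!b_hit), n_s_only = sum(!s_hit),
         b_overlap = b[b_hit], s_overlap = s[s_hit],
         b_only = b[!b_hit], s_only = s[!s_hit])
  })
  names(out) <- categories
  out
}

#' Per-region, per-sample signal matrix
#'
#' @param regions `GRanges` (will be coordinate-sorted).
#' @param tracks named list of signal `GRanges` (with `score`), one per sample.
#' @param mode `"mean"` or `"area"` (see [region_signal()]).
#' @return numeric matrix region x sample with region ids as row names.
#' @export
signal_matrix <- function(regions, tracks, mode = c("mean", "area")) {
  mode <- match.arg(mode)
  regions <- sort(regions)
  m <- vapply(tracks, function(tr) region_signal(tr, regions, mode = mode),
              numeric(length(regions)))
  matrix(m, nrow = length(regions),
         dimnames = list(region_id(regions), names(tracks)))
}
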