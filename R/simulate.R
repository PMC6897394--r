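## Seeded synthetic-data generators with planted structure. Every generator
## is deterministic given its seed and emits objects (and, via the writers,
## files) in the same formats the analysis stages consume.

## Non-overlapping placement on a slot grid: the genome is divided into
## slots of width (max region width + min_sep) and regions occupy distinct
## slots, which guarantees pairwise separation of at least min_sep so that
## stitching can never merge two distinct planted truths.
draw_slots <- function(genome, n, slot_width) {
  starts <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    if (len < slot_width) return(NULL)
    data.frame(chrom = ch,
               slot0 = seq(0, len - slot_width, by = slot_width))
  })
  slots <- do.call(rbind, starts)
  if (is.null(slots) || nrow(slots) < n) {
    stop("genome too small to place ", n, " regions with the required separation")
  }
  slots[sample.int(nrow(slots), n), , drop = FALSE]
}

#' Simulate a graded multi-sample domain panel
#'
#' Emulates a cell-line panel split into High- and Low-Grade groups, with two
#' domain types per sample: super-enhancer-like H3K27ac regions (wide,
#' high-signal) and broad-H3K4me3-like regions, plus narrow background
#' (typical) peaks. Planted `common` regions appear in every sample, `HGU`
#' regions only in High-Grade samples, `LGU` only in Low-Grade samples;
#' background peaks are placed independently per sample. Signal is
#' `signal_contrast` times baseline at planted regions with multiplicative
#' log-normal noise (`noise_sd` on the log scale); region edges are exact.
#' All placements are pairwise separated by at least twice the stitch gap,
#' so stitching cannot merge distinct truths. `n_shared` of each category
#' are planted at identical coordinates in both domain types (for overlap
#' analysis); all other placements are disjoint.
#'
#' @param n_high,n_low samples per group (defaults 3 and 4, the panel design
#'   this generator emulates).
#' @param n_common,n_hgu,n_lgu planted region counts per domain type.
#' @param n_background background (typical) peaks per sample.
#' @param n_shared named integer vector `c(common=, HGU=, LGU=)`: how many
#'   planted regions of each category coincide across the two domain types.
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param signal_contrast fold signal of planted over background regions.
#' @param noise_sd sd of log-normal multiplicative signal noise (0 = none).
#' @param stitch_gap separation guard: placements are `>= 2 * stitch_gap`
#'   apart.
#' @param seed RNG seed.
#' @return a `SimulatedPanel`: list with `marks` (per mark: named lists
#'   `peaks` and `tracks` of `GRanges` per sample), `truth` (data.frame
#'   `chrom`, `start`, `end` 0-based half-open, `category`, `domain_type`),
#'   `groups`, `params`.
#' @export
simulate_panel <- function(n_high = 3L, n_low = 4L, n_common = 38L,
                           n_hgu = 61L, n_lgu = 224L, n_background = 300L,
                           n_shared = c(common = 0L, HGU = 0L, LGU = 0L),
                           genome = c(chrA = 6e7, chrB = 6e7, chrC = 6e7, chrD = 6e7),
                           signal_contrast = 20, noise_sd = 0.25,
                           stitch_gap = 12500L, seed = 1L) {
  if (n_high < 1L || n_low < 1L) stop("need at least one sample per group")
  if (signal_contrast <= 1) stop("signal_contrast must exceed 1")
  stopifnot(all(c(n_common, n_hgu, n_lgu, n_background) >= 0))
  n_shared <- n_shared[c("common", "HGU", "LGU")]
  n_shared[is.na(n_shared)] <- 0L
  names(n_shared) <- c("common", "HGU", "LGU")
  n_cat <- c(common = n_common, HGU = n_hgu, LGU = n_lgu)
  if (any(n_shared > n_cat)) stop("n_shared cannot exceed the category counts")

  samples <- c(paste0("High", seq_len(n_high)), paste0("Low", seq_len(n_low)))
  groups <- stats::setNames(rep(c("High", "Low"), c(n_high, n_low)), samples)
  n_samples <- length(samples)
  marks <- c("H3K27ac", "H3K4me3")
  width_rng <- list(H3K27ac = c(15000L, 20000L), H3K4me3 = c(8000L, 15000L))
  bg_rng <- list(H3K27ac = c(800L, 1500L), H3K4me3 = c(800L, 2500L))
  min_sep <- 2L * stitch_gap
  slot_width <- max(unlist(width_rng)) + min_sep

  with_seed(seed, {
    n_planted_total <- sum(n_shared) + 2L * sum(n_cat - n_shared)
    n_bg_total <- 2L * n_samples * n_background
    slots <- draw_slots(genome, n_planted_total + n_bg_total, slot_width)
    cursor <- 0L
    take <- function(n) {
      out <- slots[cursor + seq_len(n), , drop = FALSE]
      cursor <<- cursor + n
      out
    }
    rand_width <- function(n, rng) sample(rng[1L]:rng[2L], n, replace = TRUE)

    ## shared planted regions: same coordinates in both marks; width drawn
    ## from the wider (H3K27ac) range so both callers see a broad region
    truth <- NULL
    planted <- list(H3K27ac = NULL, H3K4me3 = NULL)
    for (cat in names(n_cat)) {
      ns <- n_shared[[cat]]
      if (ns > 0L) {
        sl <- take(ns)
        w <- rand_width(ns, width_rng$H3K27ac)
        df <- data.frame(chrom = sl$chrom, start = sl$slot0,
                         end = sl$slot0 + w, category = cat,
                         stringsAsFactors = FALSE)
        for (mk in marks) {
          planted[[mk]] <- rbind(planted[[mk]], df)
          truth <- rbind(truth, cbind(df, domain_type = if (mk == "H3K27ac") "SE" else "broadK4"))
        }
      }
      for (mk in marks) {
        nu <- n_cat[[cat]] - ns
        if (nu > 0L) {
          sl <- take(nu)
          w <- rand_width(nu, width_rng[[mk]])
          df <- data.frame(chrom = sl$chrom, start = sl$slot0,
                           end = sl$slot0 + w, category = cat,
                           stringsAsFactors = FALSE)
          planted[[mk]] <- rbind(planted[[mk]], df)
          truth <- rbind(truth, cbind(df, domain_type = if (mk == "H3K27ac") "SE" else "broadK4"))
        }
      }
    }

    out_marks <- list()
    for (mk in marks) {
      pl <- planted[[mk]]
      pl_gr <- if (is.null(pl)) GenomicRanges::GRanges()
               else bed0_to_granges(pl$chrom, pl$start, pl$end, category = pl$category)
      peaks <- list()
      tracks <- list()
      for (smp in samples) {
        grp <- groups[[smp]]
        keep_cat <- c("common", if (grp == "High") "HGU" else "LGU")
        mine <- if (length(pl_gr)) pl_gr[S4Vectors::mcols(pl_gr)$category %in% keep_cat]
                else pl_gr
        bg <- GenomicRanges::GRanges()
        if (n_background > 0L) {
          sl <- take(n_background)
          w <- rand_width(n_background, bg_rng[[mk]])
          bg <- bed0_to_granges(sl$chrom, sl$slot0, sl$slot0 + w)
        }
        values <- c(rep(signal_contrast, length(mine)), rep(1, length(bg)))
        if (noise_sd > 0) {
          values <- values * exp(stats::rnorm(length(values), 0, noise_sd))
        }
        all_gr <- c(GenomicRanges::granges(mine), bg)
        S4Vectors::mcols(all_gr)$score <- values
        track <- sort(all_gr)
        peaks[[smp]] <- GenomicRanges::granges(track)
        tracks[[smp]] <- track
      }
      out_marks[[mk]] <- list(peaks = peaks, tracks = tracks)
    }
    structure(list(
      marks = out_marks,
      truth = truth[order(truth$domain_type, truth$category, truth$chrom, truth$start), ],
      groups = groups,
      params = list(n_high = n_high, n_low = n_low, n_common = n_common,
                    n_hgu = n_hgu, n_lgu = n_lgu, n_background = n_background,
                    n_shared = n_shared, genome = genome,
                    signal_contrast = signal_contrast, noise_sd = noise_sd,
                    stitch_gap = stitch_gap, seed = seed)
    ), class = "SimulatedPanel")
  })
}

#' @export
print.SimulatedPanel <- function(x, ...) {
  cat("SimulatedPanel:", length(x$groups), "samples,",
      nrow(x$truth), "planted regions across 2 domain types\n")
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' Emits `<sample>_<mark>.bed` and `<sample>_<mark>.bedGraph` per sample and
#' mark, `truth.tsv` and `groups.tsv`.
#'
#' @param panel a `SimulatedPanel`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "SimulatedPanel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mk in names(panel$marks)) {
    for (smp in names(panel$marks[[mk]]$peaks)) {
      write_bed(panel$marks[[mk]]$peaks[[smp]],
                file.path(dir, paste0(smp, "_", mk, ".bed")))
      write_bedgraph(panel$marks[[mk]]$tracks[[smp]],
                     file.path(dir, paste0(smp, "_", mk, ".bedGraph")))
    }
  }
  utils::write.table(panel$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(panel$groups),
                                group = unname(panel$groups)),
                     file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a blocky contact matrix with planted TADs
#'
#' Block-constant symmetric matrix: within-block cells average `contrast`
#' times the between-block level, with multiplicative log-normal noise
#' applied to the upper triangle and mirrored.
#'
#' @param tad_sizes block sizes in bins; their sum is the matrix dimension.
#' @param contrast within:between mean ratio (> 0).
#' @param noise_sd sd of log-normal noise (0.1 = 10\% multiplicative noise).
#' @param bin_size bp per bin.
#' @param chrom chromosome name.
#' @param base_value between-block mean contact level.
#' @param seed RNG seed.
#' @return list with `cm` (`ContactMatrix`), `true_boundaries` (0-based
#'   indices of each block's first bin, excluding bin 0), `tad_sizes`, `seed`.
#' @export
simulate_contact_matrix <- function(tad_sizes, contrast = 10, noise_sd = 0.1,
                                    bin_size = 40000L, chrom = "chr1",
                                    base_value = 1, seed = 1L) {
  if (any(tad_sizes < 1L)) stop("tad_sizes must be positive")
  n <- sum(tad_sizes)
  block <- rep(seq_along(tad_sizes), tad_sizes)
  same <- outer(block, block, `==`)
  mat <- base_value * ifelse(same, contrast, 1)
  if (noise_sd > 0) {
    mat <- with_seed(seed, {
      noise <- matrix(exp(stats::rnorm(n * n, 0, noise_sd)), n, n)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      mat * noise
    })
  }
  list(cm = contact_matrix(mat, bin_size = bin_size, chrom = chrom),
       true_boundaries = utils::head(cumsum(tad_sizes), -1L),
       tad_sizes = tad_sizes, seed = as.integer(seed))
}

#' Simulate treated/control region counts with planted fold-changes
#'
#' Regions are tiled along one chromosome; counts are Poisson per region and
#' replicate. Planted "increased" regions have treated mean
#' `poisson_mean * effect_fold`, "decreased" regions
#' `poisson_mean / effect_fold`; control replicates always draw at
#' `poisson_mean`.
#'
#' @param n_regions number of regions.
#' @param frac_increased,frac_decreased planted fractions (sum <= 1).
#' @param effect_fold planted fold-change (>= 1).
#' @param poisson_mean baseline Poisson mean per replicate.
#' @param n_reps replicates per condition.
#' @param chrom chromosome name for the tiled regions.
#' @param region_width,region_spacing tiling geometry in bp.
#' @param seed RNG seed.
#' @return list with `rc` (a `RegionCounts`) and `truth` (factor:
#'   increased / decreased / null).
#' @export
simulate_treatment <- function(n_regions = 2000L, frac_increased = 0.05,
                               frac_decreased = 0.05, effect_fold = 4,
                               poisson_mean = 20, n_reps = 2L,
                               chrom = "chrS", region_width = 1000L,
                               region_spacing = 2000L, seed = 1L) {
  if (frac_increased + frac_decreased > 1) stop("planted fractions sum above 1")
  if (effect_fold < 1) stop("effect_fold must be >= 1")
  ni <- round(frac_increased * n_regions)
  nd <- round(frac_decreased * n_regions)
  truth <- rep("null", n_regions)
  if (ni > 0L) truth[seq_len(ni)] <- "increased"
  if (nd > 0L) truth[ni + seq_len(nd)] <- "decreased"
  start0 <- (seq_len(n_regions) - 1L) * region_spacing
  regions <- bed0_to_granges(chrom, start0, start0 + region_width)
  lam_t <- ifelse(truth == "increased", poisson_mean * effect_fold,
                  ifelse(truth == "decreased", poisson_mean / effect_fold,
                         poisson_mean))
  counts <- with_seed(seed, {
    cbind(
      matrix(stats::rpois(n_regions * n_reps, lam_t), n_regions, n_reps),
      matrix(stats::rpois(n_regions * n_reps, poisson_mean), n_regions, n_reps)
    )
  })
  sample_names <- c(paste0("treated_", seq_len(n_reps)),
                    paste0("control_", seq_len(n_reps)))
  dimnames(counts) <- list(region_id(regions), sample_names)
  condition <- stats::setNames(rep(c("treated", "control"), each = n_reps),
                               sample_names)
  rc <- structure(list(regions = regions, counts = counts,
                       condition = condition, library_size = colSums(counts)),
                  class = "RegionCounts")
  list(rc = rc, truth = factor(truth, levels = c("increased", "decreased", "null")))
}

#' Simulate per-gene expression log2 fold-changes by category
#'
#' Genes in `affected_categories` get mean `group_effect`, all others mean 0,
#' plus Gaussian noise.
#'
#' @param category_of_gene named character vector: gene id -> category.
#' @param affected_categories categories receiving the planted effect.
#' @param group_effect planted mean log2 fold-change.
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed.
#' @return named numeric vector of log2 fold-changes along the genes.
#' @export
simulate_expression <- function(category_of_gene,
                                affected_categories = "increased",
                                group_effect = 1, noise_sd = 0.1, seed = 1L) {
  if (is.null(names(category_of_gene))) stop("category_of_gene must be named by gene")
  mu <- ifelse(category_of_gene %in% affected_categories, group_effect, 0)
  with_seed(seed, {
    stats::setNames(mu + stats::rnorm(length(mu), 0, noise_sd),
                    names(category_of_gene))
  })
}
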